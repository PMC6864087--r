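# Deterministic 3D geometry builder. Coordinates are produced by minimizing
# a distance-geometry objective (bond springs, 1-3 angle-distance springs,
# one-sided steric repulsion) from a deterministic breadth-first initial
# layout, so identical (molecule, seed) input always yields identical
# coordinates.

# Covalent radii (Cordero et al., Dalton Trans. 2008), Angstroms.
.covalent_radii <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

# Van der Waals radii (Bondi, J. Phys. Chem. 68 (1964) 441), Angstroms.
.vdw_radii <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

# Reference bond length from covalent radii, scaled by bond order.
.ref_bond_length <- function(el1, el2, order) {
  base <- .covalent_radii[[el1]] + .covalent_radii[[el2]]
  f <- if (order == 2) 0.87 else if (order == 3) 0.78
       else if (order == 1.5) 0.93 else 1
  base * f
}

# Expand a molgraph to an explicit-hydrogen atom list.
.explicit_atoms <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  el <- atoms$element
  arom <- atoms$aromatic
  b1 <- bonds$a1; b2 <- bonds$a2; bo <- bonds$order
  nheavy <- nrow(atoms)
  idx <- nheavy
  for (i in seq_len(nheavy)) {
    h <- atoms$hcount[i]
    if (h > 0L) {
      for (k in seq_len(h)) {
        idx <- idx + 1L
        el <- c(el, "H"); arom <- c(arom, FALSE)
        b1 <- c(b1, i); b2 <- c(b2, idx); bo <- c(bo, 1)
      }
    }
  }
  list(element = el, aromatic = arom,
       bonds = data.frame(a1 = b1, a2 = b2, order = bo),
       n_heavy = nheavy)
}

# All-pairs graph distances up to a cutoff (BFS per atom).
.graph_distances <- function(n, bonds, cutoff = 3L) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0L && depth < cutoff) {
      depth <- depth + 1L
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Deterministic pseudo-random numbers in [-0.5, 0.5] (integer hash; keeps the
# global RNG untouched).
.det_jitter <- function(seed, n) {
  x <- ((as.double(seed) * 2654435761 + seq_len(n) * 40503) %% 104729) / 104729
  x - 0.5
}

#' Generate a deterministic 3D conformer
#'
#' Embeds the parent fragment (with explicit hydrogens) in 3D by minimizing a
#' distance-geometry objective: bonded atoms are pulled to reference bond
#' lengths (covalent-radius sums, scaled by bond order), geminal atoms to
#' ideal-angle distances (109.47 degrees for sp3, 120 for sp2/aromatic, 180
#' for sp centers), and non-bonded atoms repelled below a fraction of their
#' van der Waals contact distance. The initial layout and a small coordinate
#' jitter are derived deterministically from `seed`, and the optimizer
#' (L-BFGS-B with analytic gradients) is deterministic, so identical
#' `(mol, seed)` input reproduces identical coordinates.
#'
#' @param mol A `molgraph` or SMILES string (at most 200 atoms including
#'   hydrogens).
#' @param seed Integer seed for the initial layout.
#' @param max_retries Embedding attempts with re-jittered starts before
#'   giving up.
#' @return A `conformer3d`: list with `coords` (n x 3 matrix, Angstroms),
#'   `element`, `radius` (van der Waals, Angstroms), `n_heavy`, `seed`.
#' @export
generate_conformer <- function(mol, seed = 7L, max_retries = 5L) {
  mol <- parent_fragment(.as_molgraph(mol))
  ex <- .explicit_atoms(mol)
  n <- length(ex$element)
  if (n > 200L) stop("molecule too large to embed (> 200 atoms)",
                     call. = FALSE)
  if (any(!ex$element %in% names(.covalent_radii)))
    stop("no covalent radius for element ",
         setdiff(ex$element, names(.covalent_radii))[1], call. = FALSE)

  # hybridization per heavy atom (for angle targets)
  env <- .atom_env(mol)
  hyb <- vapply(seq_len(ex$n_heavy), function(i) .hybridization(env[[i]]),
                "")
  hyb <- c(hyb, rep("sp3", n - ex$n_heavy))

  bonds <- ex$bonds
  d0 <- vapply(seq_len(nrow(bonds)), function(k) {
    .ref_bond_length(ex$element[bonds$a1[k]], ex$element[bonds$a2[k]],
                     bonds$order[k])
  }, 0)

  # 1-3 targets via law of cosines around each center atom
  adj <- vector("list", n)
  blen <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
    blen[[bonds$a1[k]]] <- c(blen[[bonds$a1[k]]], d0[k])
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
    blen[[bonds$a2[k]]] <- c(blen[[bonds$a2[k]]], d0[k])
  }
  ai <- integer(0); aj <- integer(0); at <- numeric(0)
  for (c0 in seq_len(n)) {
    nb <- adj[[c0]]
    if (length(nb) < 2L) next
    theta <- switch(hyb[c0], sp = pi, sp2 = 2 * pi / 3,
                    109.47 * pi / 180)
    for (p in seq_len(length(nb) - 1L)) {
      for (q in seq((p + 1L), length(nb))) {
        ai <- c(ai, nb[p]); aj <- c(aj, nb[q])
        l1 <- blen[[c0]][p]; l2 <- blen[[c0]][q]
        at <- c(at, sqrt(l1^2 + l2^2 - 2 * l1 * l2 * cos(theta)))
      }
    }
  }

  gd <- .graph_distances(n, bonds, cutoff = 3L)
  vdw <- .vdw_radii[ex$element]
  # non-bonded lower bounds: softer for 1-4 pairs, firmer beyond
  ri <- integer(0); rj <- integer(0); rmin <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (gd[i, j] <= 2) next
      f <- if (gd[i, j] == 3) 0.80 else 0.90
      ri <- c(ri, i); rj <- c(rj, j)
      rmin <- c(rmin, f * (vdw[i] + vdw[j]))
    }
  }

  w_bond <- 100; w_ang <- 40; w_rep <- 15
  b1 <- bonds$a1; b2 <- bonds$a2

  objective <- function(p) {
    x <- matrix(p, ncol = 3)
    db <- x[b1, , drop = FALSE] - x[b2, , drop = FALSE]
    lb <- sqrt(rowSums(db^2))
    da <- x[ai, , drop = FALSE] - x[aj, , drop = FALSE]
    la <- sqrt(rowSums(da^2))
    dr <- x[ri, , drop = FALSE] - x[rj, , drop = FALSE]
    lr <- sqrt(rowSums(dr^2))
    viol <- pmax(0, rmin - lr)
    w_bond * sum((lb - d0)^2) + w_ang * sum((la - at)^2) +
      w_rep * sum(viol^2)
  }
  gradient <- function(p) {
    x <- matrix(p, ncol = 3)
    g <- matrix(0, nrow(x), 3)
    db <- x[b1, , drop = FALSE] - x[b2, , drop = FALSE]
    lb <- pmax(sqrt(rowSums(db^2)), 1e-8)
    cb <- 2 * w_bond * (lb - d0) / lb
    gb <- db * cb
    for (c3 in 1:3) {
      g[, c3] <- g[, c3] +
        tabulate_add(b1, gb[, c3], nrow(x)) -
        tabulate_add(b2, gb[, c3], nrow(x))
    }
    da <- x[ai, , drop = FALSE] - x[aj, , drop = FALSE]
    la <- pmax(sqrt(rowSums(da^2)), 1e-8)
    ca <- 2 * w_ang * (la - at) / la
    ga <- da * ca
    for (c3 in 1:3) {
      g[, c3] <- g[, c3] +
        tabulate_add(ai, ga[, c3], nrow(x)) -
        tabulate_add(aj, ga[, c3], nrow(x))
    }
    dr <- x[ri, , drop = FALSE] - x[rj, , drop = FALSE]
    lr <- pmax(sqrt(rowSums(dr^2)), 1e-8)
    viol <- pmax(0, rmin - lr)
    cr <- -2 * w_rep * viol / lr
    gr <- dr * cr
    for (c3 in 1:3) {
      g[, c3] <- g[, c3] +
        tabulate_add(ri, gr[, c3], nrow(x)) -
        tabulate_add(rj, gr[, c3], nrow(x))
    }
    as.vector(g)
  }

  for (attempt in seq_len(max_retries)) {
    x0 <- .initial_layout(n, adj, blen, seed + (attempt - 1L) * 1000L)
    opt <- stats::optim(as.vector(x0), objective, gradient,
                        method = "L-BFGS-B",
                        control = list(maxit = 2000L, factr = 1e4))
    coords <- matrix(opt$par, ncol = 3)
    lb <- sqrt(rowSums((coords[b1, , drop = FALSE] -
                          coords[b2, , drop = FALSE])^2))
    bond_ok <- all(abs(lb - d0) / d0 <= 0.15)
    clash_ok <- TRUE
    if (length(ri) > 0L) {
      lr <- sqrt(rowSums((coords[ri, , drop = FALSE] -
                            coords[rj, , drop = FALSE])^2))
      clash_ok <- all(lr >= 0.7 * (vdw[ri] + vdw[rj]))
    }
    if (bond_ok && clash_ok) {
      out <- list(coords = coords, element = ex$element,
                  radius = unname(vdw), n_heavy = ex$n_heavy, seed = seed)
      class(out) <- "conformer3d"
      return(out)
    }
  }
  stop("3D embedding failed after ", max_retries, " attempts", call. = FALSE)
}

# base-R scatter-add
tabulate_add <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Deterministic breadth-first initial layout: each atom is placed at bond
# length from its BFS parent in the candidate direction (from a fixed
# icosahedral direction set) farthest from the already-placed atoms.
.initial_layout <- function(n, adj, blen, seed) {
  phi <- (1 + sqrt(5)) / 2
  dirs <- rbind(
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1),
    c(-1, 1, 1), c(-1, 1, -1), c(-1, -1, 1), c(-1, -1, -1),
    c(0, 1 / phi, phi), c(0, 1 / phi, -phi), c(0, -1 / phi, phi),
    c(0, -1 / phi, -phi),
    c(1 / phi, phi, 0), c(1 / phi, -phi, 0), c(-1 / phi, phi, 0),
    c(-1 / phi, -phi, 0),
    c(phi, 0, 1 / phi), c(phi, 0, -1 / phi), c(-phi, 0, 1 / phi),
    c(-phi, 0, -1 / phi)
  )
  dirs <- dirs / sqrt(rowSums(dirs^2))
  x <- matrix(NA_real_, n, 3)
  placed <- logical(n)
  for (root in seq_len(n)) {
    if (placed[root]) next
    offset <- sum(placed)
    x[root, ] <- c(offset * 5, 0, 0)  # separate fragments
    placed[root] <- TRUE
    queue <- root
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      nbrs <- adj[[v]]
      for (kk in seq_along(nbrs)) {
        w <- nbrs[kk]
        if (placed[w]) next
        L <- blen[[v]][kk]
        cand <- sweep(dirs * L, 2, x[v, ], `+`)
        others <- x[placed, , drop = FALSE]
        score <- apply(cand, 1, function(pp) {
          min(sqrt(rowSums(sweep(others, 2, pp)^2)))
        })
        best <- which.max(score)
        x[w, ] <- cand[best, ]
        placed[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  x + 0.05 * matrix(.det_jitter(seed, 3 * n), n, 3)
}

#' @export
print.conformer3d <- function(x, ...) {
  cat(sprintf("<conformer3d> %d atoms (%d heavy), seed %d\n",
              nrow(x$coords), x$n_heavy, x$seed))
  invisible(x)
}
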
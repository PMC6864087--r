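# Organic-subset default valences used for implicit hydrogen assignment.
# For N, P, S the smallest allowed valence >= the explicit bond order sum wins.
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

.organic_subset <- names(.default_valences)

#' Parse a SMILES string into a molecular graph
#'
#' Builds an explicit atom/bond graph from a SMILES string: elements, formal
#' charges, aromatic flags, attached-hydrogen counts and ring membership per
#' atom; order and endpoints per bond. Multi-fragment (salt) notation with
#' `.` separators is supported; the largest organic fragment is flagged as
#' the parent and counterions are retained but marked.
#'
#' Aromaticity is taken from the input (lowercase aromatic atoms and `:`
#' bonds); kekulized aromatic input is not re-perceived. Implicit hydrogens
#' on organic-subset atoms follow the usual default-valence rules, with
#' aromatic bonds counted at order 1.5 and the bond-order sum rounded up.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `molgraph`: a list with data frames `atoms`
#'   (columns `element`, `aromatic`, `charge`, `hcount`, `degree`, `in_ring`,
#'   `fragment`, `is_parent`) and `bonds` (columns `a1`, `a2`, `order`,
#'   `aromatic`, `in_ring`), plus `n_fragments`.
#' @examples
#' mol <- parse_structure("c1ccccc1")
#' sum(mol$atoms$hcount)  # 6 implicit hydrogens on benzene
#' @export
parse_structure <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  toks <- .tokenize_smiles(smiles)
  .build_molgraph(toks, smiles)
}

.parse_error <- function(smiles, pos, msg) {
  cond <- structure(
    class = c("smiles_parse_error", "error", "condition"),
    list(message = sprintf("SMILES parse error at position %d ('%s'): %s",
                           pos, substr(smiles, pos, pos), msg),
         call = NULL, position = pos, smiles = smiles)
  )
  stop(cond)
}

# Tokenizer: returns a list of tokens with type, value, position.
.tokenize_smiles <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- vector("list", n)
  nt <- 0L
  i <- 1L
  push <- function(type, value, pos) {
    nt <<- nt + 1L
    toks[[nt]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .parse_error(smiles, i, "unterminated bracket atom")
      push("bracket", substr(smiles, i, j), i)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      push("atom", paste0(ch, chars[i + 1L]), i)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      push("atom", ch, i)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      push("aromatic_atom", ch, i)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      push("bond", ch, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L)))
        .parse_error(smiles, i, "'%' must be followed by two digits")
      push("ring", substr(smiles, i + 1L, i + 2L), i)
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      push("ring", ch, i)
      i <- i + 1L
    } else if (ch == "(") {
      push("open", ch, i)
      i <- i + 1L
    } else if (ch == ")") {
      push("close", ch, i)
      i <- i + 1L
    } else if (ch == ".") {
      push("dot", ch, i)
      i <- i + 1L
    } else {
      .parse_error(smiles, i, "unrecognized character")
    }
  }
  toks[seq_len(nt)]
}

# Parse a bracket atom token body like "[NH3+]", "[O-]", "[13CH4]".
.parse_bracket <- function(body, pos, smiles) {
  inner <- substr(body, 2L, nchar(body) - 1L)
  m <- regexec(
    "^([0-9]*)([A-Z][a-z]?|[bcnops])(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+{2,}|-{2,})?(:[0-9]+)?$",
    inner)
  g <- regmatches(inner, m)[[1]]
  if (length(g) == 0L) .parse_error(smiles, pos, "malformed bracket atom")
  sym <- g[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  element <- if (aromatic) toupper(sym) else sym
  hpart <- g[5]
  hcount <- if (is.na(hpart) || hpart == "") 0L
            else if (hpart == "H") 1L
            else as.integer(substr(hpart, 2L, nchar(hpart)))
  cpart <- g[6]
  charge <- 0L
  if (!is.na(cpart) && nzchar(cpart)) {
    if (grepl("^\\+{2,}$", cpart)) charge <- nchar(cpart)
    else if (grepl("^-{2,}$", cpart)) charge <- -nchar(cpart)
    else if (cpart == "+") charge <- 1L
    else if (cpart == "-") charge <- -1L
    else charge <- as.integer(cpart)
  }
  list(element = element, aromatic = aromatic, hcount = hcount,
       charge = charge, explicit_h = TRUE)
}

.build_molgraph <- function(toks, smiles) {
  atoms <- list()
  bonds <- list()
  na <- 0L; nb <- 0L
  prev <- NA_integer_
  pending_bond <- NA_character_
  stack <- integer(0)
  ring_open <- list()   # digit -> list(atom, bond, pos)
  frag <- 1L

  add_atom <- function(a) {
    na <<- na + 1L
    a$fragment <- frag
    atoms[[na]] <<- a
    na
  }
  add_bond <- function(a1, a2, sym, arom_pair) {
    order <- switch(ifelse(is.na(sym), "implicit", sym),
      "-" = 1, "/" = 1, "\\" = 1, "=" = 2, "#" = 3, "$" = 4,
      ":" = 1.5, "implicit" = if (arom_pair) 1.5 else 1)
    nb <<- nb + 1L
    bonds[[nb]] <<- list(a1 = a1, a2 = a2, order = order,
                         aromatic = identical(order, 1.5))
  }

  for (tk in toks) {
    if (tk$type %in% c("atom", "aromatic_atom", "bracket")) {
      a <- if (tk$type == "bracket") {
        .parse_bracket(tk$value, tk$pos, smiles)
      } else {
        list(element = if (tk$type == "aromatic_atom") toupper(tk$value)
                       else tk$value,
             aromatic = tk$type == "aromatic_atom",
             hcount = NA_integer_, charge = 0L, explicit_h = FALSE)
      }
      idx <- add_atom(a)
      if (!is.na(prev)) {
        arom_pair <- isTRUE(atoms[[prev]]$aromatic) && isTRUE(a$aromatic)
        add_bond(prev, idx, pending_bond, arom_pair)
      }
      prev <- idx
      pending_bond <- NA_character_
    } else if (tk$type == "bond") {
      if (is.na(prev)) .parse_error(smiles, tk$pos, "bond with no preceding atom")
      pending_bond <- tk$value
    } else if (tk$type == "ring") {
      if (is.na(prev)) .parse_error(smiles, tk$pos, "ring closure with no preceding atom")
      key <- tk$value
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        if (op$atom == prev)
          .parse_error(smiles, tk$pos, "ring closure bonds an atom to itself")
        sym <- if (!is.na(pending_bond)) pending_bond else op$bond
        arom_pair <- isTRUE(atoms[[op$atom]]$aromatic) &&
                     isTRUE(atoms[[prev]]$aromatic)
        add_bond(op$atom, prev, sym, arom_pair)
        ring_open[[key]] <- NULL
        pending_bond <- NA_character_
      } else {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond, pos = tk$pos)
        pending_bond <- NA_character_
      }
    } else if (tk$type == "open") {
      if (is.na(prev)) .parse_error(smiles, tk$pos, "branch with no preceding atom")
      stack <- c(stack, prev)
    } else if (tk$type == "close") {
      if (length(stack) == 0L) .parse_error(smiles, tk$pos, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tk$type == "dot") {
      prev <- NA_integer_
      pending_bond <- NA_character_
      frag <- frag + 1L
    }
  }
  if (length(stack) > 0L)
    .parse_error(smiles, nchar(smiles), "unmatched '('")
  if (length(ring_open) > 0L) {
    op <- ring_open[[1]]
    .parse_error(smiles, op$pos, "unclosed ring bond")
  }
  if (na == 0L) .parse_error(smiles, 1L, "no atoms")

  atoms_df <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    hcount = vapply(atoms, function(a) as.integer(a$hcount), 0L),
    explicit_h = vapply(atoms, `[[`, FALSE, "explicit_h"),
    fragment = vapply(atoms, function(a) as.integer(a$fragment), 0L),
    stringsAsFactors = FALSE
  )
  bonds_df <- if (nb > 0L) {
    data.frame(
      a1 = vapply(bonds, function(b) as.integer(b$a1), 0L),
      a2 = vapply(bonds, function(b) as.integer(b$a2), 0L),
      order = vapply(bonds, `[[`, 0, "order"),
      aromatic = vapply(bonds, `[[`, FALSE, "aromatic")
    )
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0),
               aromatic = logical(0))
  }

  mol <- .perceive(atoms_df, bonds_df, smiles)
  mol$smiles <- smiles
  class(mol) <- "molgraph"
  mol
}

# Degree, implicit H, ring membership, parent-fragment flag.
.perceive <- function(atoms, bonds, smiles) {
  n <- nrow(atoms)
  deg <- integer(n)
  osum <- numeric(n)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      osum[i] <- osum[i] + bonds$order[k]
      osum[j] <- osum[j] + bonds$order[k]
    }
  }
  atoms$degree <- deg

  for (i in seq_len(n)) {
    if (atoms$explicit_h[i]) next  # bracket atoms: H count as written
    el <- atoms$element[i]
    if (!el %in% .organic_subset) {
      atoms$hcount[i] <- 0L
      next
    }
    need <- ceiling(osum[i] - 1e-9)
    vals <- .default_valences[[el]]
    v <- vals[vals >= need][1]
    if (is.na(v)) v <- need  # hypervalent as written; no implicit H
    h <- as.integer(v - need)
    if (h < 0L) h <- 0L
    atoms$hcount[i] <- h
  }

  ring_bond <- .ring_bonds(n, bonds)
  bonds$in_ring <- ring_bond
  in_ring <- logical(n)
  if (any(ring_bond)) {
    rb <- bonds[ring_bond, , drop = FALSE]
    in_ring[unique(c(rb$a1, rb$a2))] <- TRUE
  }
  atoms$in_ring <- in_ring

  # Parent fragment: most heavy atoms; ties broken by carbon count then index.
  frags <- sort(unique(atoms$fragment))
  heavy <- vapply(frags, function(f) sum(atoms$fragment == f), 0L)
  carbons <- vapply(frags, function(f)
    sum(atoms$fragment == f & atoms$element == "C"), 0L)
  ord <- order(-heavy, -carbons, frags)
  parent <- frags[ord[1]]
  atoms$is_parent <- atoms$fragment == parent

  list(atoms = atoms, bonds = bonds, n_fragments = length(frags))
}

# Bonds that lie on a cycle (non-bridges), via iterative DFS bridge finding.
.ring_bonds <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0L) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
  }
  other <- function(k, v) if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
  disc <- integer(n); low <- integer(n)
  is_bridge <- logical(m)
  timer <- 0L
  visited <- logical(n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    # iterative DFS: stack of (vertex, parent-edge, next-neighbor-index)
    stack_v <- root; stack_pe <- NA_integer_; stack_ni <- 1L
    visited[root] <- TRUE; timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack_v) > 0L) {
      top <- length(stack_v)
      v <- stack_v[top]; pe <- stack_pe[top]; ni <- stack_ni[top]
      edges <- adj[[v]]
      if (ni <= length(edges)) {
        stack_ni[top] <- ni + 1L
        k <- edges[ni]
        if (!is.na(pe) && k == pe) next
        w <- other(k, v)
        if (!visited[w]) {
          visited[w] <- TRUE; timer <- timer + 1L
          disc[w] <- low[w] <- timer
          stack_v <- c(stack_v, w)
          stack_pe <- c(stack_pe, k)
          stack_ni <- c(stack_ni, 1L)
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        stack_v <- stack_v[-top]; stack_pe <- stack_pe[-top]
        stack_ni <- stack_ni[-top]
        if (!is.na(pe)) {
          u <- if (length(stack_v) > 0L) stack_v[length(stack_v)] else NA_integer_
          if (!is.na(u)) {
            low[u] <- min(low[u], low[v])
            if (low[v] > disc[u]) is_bridge[pe] <- TRUE
          }
        }
      }
    }
  }
  !is_bridge
}

#' @export
print.molgraph <- function(x, ...) {
  natoms <- nrow(x$atoms)
  cat(sprintf("<molgraph> %d heavy atoms, %d bonds, %d fragment%s\n",
              natoms, nrow(x$bonds), x$n_fragments,
              if (x$n_fragments == 1L) "" else "s"))
  if (x$n_fragments > 1L) {
    cat(sprintf("  parent fragment: %d atoms; counterion(s) marked\n",
                sum(x$atoms$is_parent)))
  }
  invisible(x)
}

# Neighbor index list (heavy atoms only; graph has no explicit H rows).
.neighbors <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  adj
}

# Bond lookup: list indexed like .neighbors but giving bond row indices.
.incident_bonds <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], k)
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], k)
  }
  adj
}

#' Extract the parent fragment of a molecule
#'
#' Returns a new `molgraph` containing only the parent (largest) fragment,
#' with atom indices remapped. Formal charges on the parent are preserved, so
#' a permanently charged parent (e.g. a quaternary ammonium cation) stays an
#' ion after its counterion is stripped.
#'
#' @param mol A `molgraph`.
#' @return A `molgraph` with a single fragment.
#' @export
parent_fragment <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  if (mol$n_fragments == 1L) return(mol)
  keep <- which(mol$atoms$is_parent)
  map <- integer(nrow(mol$atoms))
  map[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bsel <- mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep
  bonds <- mol$bonds[bsel, , drop = FALSE]
  bonds$a1 <- map[bonds$a1]; bonds$a2 <- map[bonds$a2]
  rownames(bonds) <- NULL
  atoms$fragment <- 1L
  out <- list(atoms = atoms, bonds = bonds, n_fragments = 1L,
              smiles = mol$smiles)
  class(out) <- "molgraph"
  out
}

#' Write a molecular graph back to SMILES
#'
#' Emits a (non-canonical) SMILES string by depth-first traversal. Atoms are
#' written in the organic subset where the implied implicit-hydrogen count
#' matches the stored one; otherwise a bracket atom with explicit H count and
#' charge is written. Use [canonical_smiles()] for a canonical form.
#'
#' @param mol A `molgraph`.
#' @return A SMILES string.
#' @export
write_smiles <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  atoms <- mol$atoms; bonds <- mol$bonds
  n <- nrow(atoms)
  inc <- .incident_bonds(mol)

  bond_sym <- function(k) {
    o <- bonds$order[k]
    if (o == 2) "=" else if (o == 3) "#" else ""
  }
  atom_token <- function(i) {
    el <- atoms$element[i]
    sym <- if (atoms$aromatic[i]) tolower(el) else el
    if (el %in% .organic_subset && atoms$charge[i] == 0L) {
      osum <- sum(bonds$order[inc[[i]]])
      need <- ceiling(osum - 1e-9)
      vals <- .default_valences[[el]]
      v <- vals[vals >= need][1]
      implied <- if (is.na(v)) 0L else as.integer(v - need)
      if (identical(implied, atoms$hcount[i])) return(sym)
    }
    h <- atoms$hcount[i]
    hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ch <- atoms$charge[i]
    cstr <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
            else sprintf("%+d", ch)
    paste0("[", sym, hstr, cstr, "]")
  }

  # pass 1: spanning forest (DFS) + ring-closure bonds
  visited <- logical(n)
  bond_used <- logical(nrow(bonds))
  tree_children <- vector("list", n)
  ring_closures <- integer(0)
  roots <- integer(0)
  for (start in seq_len(n)) {
    if (visited[start]) next
    roots <- c(roots, start)
    stack <- start
    visited[start] <- TRUE
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (k in inc[[v]]) {
        if (bond_used[k]) next
        j <- if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
        if (!visited[j]) {
          visited[j] <- TRUE
          bond_used[k] <- TRUE
          tree_children[[v]] <- c(tree_children[[v]], k)
          stack <- c(stack, j)
        } else {
          bond_used[k] <- TRUE
          ring_closures <- c(ring_closures, k)
        }
      }
    }
  }
  closure_at <- vector("list", n)
  for (idx in seq_along(ring_closures)) {
    k <- ring_closures[idx]
    lab <- if (idx < 10L) as.character(idx) else paste0("%", sprintf("%02d", idx))
    for (v in c(bonds$a1[k], bonds$a2[k])) {
      closure_at[[v]] <- c(closure_at[[v]], list(list(lab = lab, k = k)))
    }
  }

  # pass 2: recursive emission over the spanning forest
  write_atom <- function(v) {
    out <- atom_token(v)
    for (cl in closure_at[[v]]) out <- paste0(out, bond_sym(cl$k), cl$lab)
    ks <- tree_children[[v]]
    if (length(ks) > 0L) {
      parts <- vapply(ks, function(k) {
        j <- if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
        paste0(bond_sym(k), write_atom(j))
      }, "")
      last <- length(parts)
      if (last > 1L)
        out <- paste0(out, paste0("(", parts[-last], ")", collapse = ""))
      out <- paste0(out, parts[last])
    }
    out
  }
  paste(vapply(roots, function(r) write_atom(r), ""), collapse = ".")
}

#' Canonical SMILES
#'
#' Canonicalization is delegated to Open Babel (via \pkg{ChemmineOB}), which
#' provides a stable canonical atom ranking. Accepts a SMILES string or a
#' `molgraph` (which is first serialized with [write_smiles()]).
#'
#' @param x A SMILES string (vectorized) or a `molgraph`.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(x) {
  if (inherits(x, "molgraph")) x <- write_smiles(x)
  stopifnot(is.character(x))
  out <- vapply(x, function(smi) {
    res <- ChemmineOB::convertFormat("SMILES", "CAN", paste0(smi, "\n"))
    sub("[ \t\n].*$", "", res)
  }, "", USE.NAMES = FALSE)
  out
}
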
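# Structure-activity analysis: pharmacophore flags from structure, activity
# calls from viability, region-wise matched pairs, necessity/sufficiency rule
# induction, and four-parameter logistic dose-response fits.

#' Pharmacophore flags from structure
#'
#' Derives the boolean structural requirements discussed for the BPA series
#' from the parent fragment alone: a diaryl-ketone (benzophenone) carbonyl
#' linker; a chlorine para to the ring attachment point on an aromatic ring;
#' the alpha-carbon methyl count (gem-dimethyl / monomethyl / unsubstituted);
#' the amide nitrogen substitution class; and a permanently charged
#' quaternary nitrogen.
#'
#' @param mol A `molgraph` or SMILES string.
#' @return List with `carbonyl_linker`, `para_chloro`, `gem_dimethyl`,
#'   `alpha_methyl_count`, `amide_class` (one of `primary`, `secondary`,
#'   `tertiary`, `ester`, `acid`, `none`) and `permanent_cation`.
#' @examples
#' substructure_flags("OCCN(C)C(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1")
#' @export
substructure_flags <- function(mol) {
  mol <- parent_fragment(.as_molgraph(mol))
  env <- .atom_env(mol)
  nbrs <- .neighbors(mol)
  atoms <- mol$atoms

  is_carbonyl_c <- vapply(env, function(e) {
    e$el == "C" && !e$arom &&
      any(e$bond_order == 2 & e$nbr_el == "O" & !e$nbr_arom)
  }, FALSE)

  # diaryl ketone: carbonyl carbon with two aromatic carbon neighbors
  carbonyl_linker <- any(vapply(which(is_carbonyl_c), function(i) {
    e <- env[[i]]
    sum(e$nbr_arom & e$nbr_el == "C" & e$bond_order == 1) >= 2
  }, FALSE))

  # chlorine para to a substituted ring position (in-ring distance 3 over
  # aromatic ring bonds)
  para_chloro <- FALSE
  ring_bond_sel <- mol$bonds$in_ring & mol$bonds$aromatic
  radj <- vector("list", nrow(atoms))
  if (any(ring_bond_sel)) {
    rb <- mol$bonds[ring_bond_sel, , drop = FALSE]
    for (k in seq_len(nrow(rb))) {
      radj[[rb$a1[k]]] <- c(radj[[rb$a1[k]]], rb$a2[k])
      radj[[rb$a2[k]]] <- c(radj[[rb$a2[k]]], rb$a1[k])
    }
  }
  cl_on_ring <- which(vapply(seq_len(nrow(atoms)), function(i) {
    atoms$element[i] == "Cl" &&
      any(atoms$aromatic[nbrs[[i]]] & atoms$in_ring[nbrs[[i]]])
  }, FALSE))
  for (cl in cl_on_ring) {
    a0 <- nbrs[[cl]][atoms$aromatic[nbrs[[cl]]]][1]
    # BFS over aromatic ring bonds from the Cl-bearing carbon
    dist <- rep(NA_integer_, nrow(atoms))
    dist[a0] <- 0L
    frontier <- a0
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(radj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (length(nxt) == 0L) break
      dist[nxt] <- dist[frontier[1]] + 1L
      frontier <- nxt
    }
    para_atoms <- which(!is.na(dist) & dist == 3L)
    for (p in para_atoms) {
      subst <- setdiff(nbrs[[p]], which(!is.na(dist)))
      if (length(subst) > 0L) {
        para_chloro <- TRUE
        break
      }
    }
    if (para_chloro) break
  }

  # alpha carbon: aliphatic C bonded to an aryl ether oxygen and to a
  # carbonyl carbon
  alpha_methyl_count <- NA_integer_
  for (i in seq_len(nrow(atoms))) {
    e <- env[[i]]
    if (e$el != "C" || e$arom) next
    has_aryl_o <- any(vapply(seq_along(e$nbr_idx), function(k) {
      e$nbr_el[k] == "O" && !e$nbr_arom[k] && e$bond_order[k] == 1 &&
        any(env[[e$nbr_idx[k]]]$nbr_arom)
    }, FALSE))
    has_acyl <- any(e$nbr_idx %in% which(is_carbonyl_c))
    if (has_aryl_o && has_acyl) {
      methyls <- sum(vapply(seq_along(e$nbr_idx), function(k) {
        j <- e$nbr_idx[k]
        e$nbr_el[k] == "C" && !e$nbr_arom[k] && env[[j]]$h == 3L
      }, FALSE))
      alpha_methyl_count <- methyls
      break
    }
  }
  gem_dimethyl <- !is.na(alpha_methyl_count) && alpha_methyl_count >= 2L

  # amide class from the acyl group
  amide_class <- "none"
  for (i in which(is_carbonyl_c)) {
    e <- env[[i]]
    n_k <- which(e$nbr_el == "N" & e$bond_order == 1 & !e$nbr_arom)
    if (length(n_k) > 0L) {
      nn <- env[[e$nbr_idx[n_k[1]]]]
      others <- length(nn$nbr_idx) - 1L  # substituents besides the acyl C
      amide_class <- if (others >= 2L) "tertiary"
                     else if (others == 1L) "secondary" else "primary"
      break
    }
    o_k <- which(e$nbr_el == "O" & e$bond_order == 1 & !e$nbr_arom)
    for (ok in o_k) {
      oe <- env[[e$nbr_idx[ok]]]
      if (oe$h >= 1L) { amide_class <- "acid"; break }
      if (length(oe$nbr_idx) == 2L) {
        other <- setdiff(oe$nbr_idx, i)
        # ester only if the O-alkyl carbon is not part of the aryl ether
        if (atoms$element[other] == "C" && !atoms$aromatic[other])
          amide_class <- "ester"
      }
    }
    if (amide_class %in% c("acid", "ester")) break
  }

  permanent_cation <- any(vapply(env, function(e) {
    e$el == "N" && e$charge > 0 && e$h == 0L && e$n_single == 4
  }, FALSE))

  list(carbonyl_linker = carbonyl_linker,
       para_chloro = para_chloro,
       gem_dimethyl = gem_dimethyl,
       alpha_methyl_count = alpha_methyl_count,
       amide_class = amide_class,
       permanent_cation = permanent_cation)
}

#' Call a compound active or inactive from cell viability
#'
#' A compound is called active when its mean cell viability at the reference
#' concentration is at or below the threshold (default: 50% of vehicle
#' control at 25 uM).
#'
#' @param cv data.frame of viability records (`concentration_um`, `mean_cv`)
#'   for one compound.
#' @param threshold Activity threshold, % of control.
#' @param concentration Reference concentration, uM.
#' @return `TRUE` if active.
#' @export
call_activity <- function(cv, threshold = 50, concentration = 25) {
  rows <- which(cv$concentration_um == concentration)
  if (length(rows) == 0L)
    stop("no viability record at ", concentration, " uM", call. = FALSE)
  mean(cv$mean_cv[rows]) <= threshold
}

#' Region-wise matched pairs
#'
#' All unordered compound pairs identical in three modification regions and
#' differing in the named one, with the viability difference at the
#' reference concentration where both compounds have a record.
#'
#' @param lib A `bpa_library` (region tag columns required).
#' @param region One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param concentration Reference concentration for the CV delta, uM.
#' @return data.frame with `region`, `id_a`, `id_b` (lexicographic),
#'   `tag_a`, `tag_b`, `cv_a`, `cv_b`, `delta_cv` (cv_b - cv_a).
#' @export
matched_pairs <- function(lib, region = c("A", "B", "C", "D"),
                          concentration = 25) {
  region <- match.arg(region)
  comp <- lib$compounds
  regcols <- c(A = "region_a", B = "region_b", C = "region_c",
               D = "region_d")
  vary <- regcols[[region]]
  fixed <- setdiff(unname(regcols), vary)
  cv_at <- function(id) {
    rows <- lib$cv$compound_id == id &
      lib$cv$concentration_um == concentration
    if (any(rows)) mean(lib$cv$mean_cv[rows]) else NA_real_
  }
  out <- list()
  n <- nrow(comp)
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq((i + 1L), n)) {
      if (n < 2L) break
      same_fixed <- all(comp[i, fixed] == comp[j, fixed])
      differs <- comp[i, vary] != comp[j, vary]
      if (!same_fixed || !differs) next
      ord <- order(c(comp$id[i], comp$id[j]))
      ids <- c(comp$id[i], comp$id[j])[ord]
      tags <- c(comp[[vary]][i], comp[[vary]][j])[ord]
      cva <- cv_at(ids[1]); cvb <- cv_at(ids[2])
      out[[length(out) + 1L]] <- data.frame(
        region = region, id_a = ids[1], id_b = ids[2],
        tag_a = tags[1], tag_b = tags[2],
        cv_a = cva, cv_b = cvb, delta_cv = cvb - cva,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(region = character(0), id_a = character(0),
                      id_b = character(0), tag_a = character(0),
                      tag_b = character(0), cv_a = numeric(0),
                      cv_b = numeric(0), delta_cv = numeric(0)))
  do.call(rbind, out)
}

# Boolean candidate features from a flags table (amide class handled
# ordinally: tertiary > secondary > primary).
.rule_features <- function(flags) {
  data.frame(
    carbonyl_linker = as.logical(flags$carbonyl_linker),
    para_chloro = as.logical(flags$para_chloro),
    gem_dimethyl = as.logical(flags$gem_dimethyl),
    amide_ge_tertiary = flags$amide_class == "tertiary",
    amide_ge_secondary = flags$amide_class %in% c("tertiary", "secondary"),
    permanent_cation = as.logical(flags$permanent_cation)
  )
}

#' Induce a pharmacophore rule from flags and activity labels
#'
#' For each candidate structural feature computes its necessity
#' P(flag | active) and sufficiency gap P(active | flag) - P(active | !flag).
#' The rule is the set of features with necessity >= `necessity_min` and a
#' positive sufficiency gap. The amide class is handled ordinally: if
#' "at least tertiary" qualifies it is reported, otherwise "at least
#' secondary" is considered.
#'
#' @param flags data.frame of per-compound flags (as from
#'   [substructure_flags()], one row per compound: columns
#'   `carbonyl_linker`, `para_chloro`, `gem_dimethyl`, `amide_class`,
#'   `permanent_cation`).
#' @param activity Logical vector of activity calls.
#' @param necessity_min Necessity threshold, default 0.9.
#' @param min_n Minimum number of labelled compounds, default 10.
#' @return A `pharmacophore_rule`: list with `required` (character vector of
#'   feature names) and `stats` (per-feature necessity/sufficiency table).
#' @export
induce_rule <- function(flags, activity, necessity_min = 0.9, min_n = 10L) {
  stopifnot(nrow(flags) == length(activity))
  if (length(activity) < min_n)
    stop("need at least ", min_n, " labelled compounds", call. = FALSE)
  if (all(activity) || all(!activity))
    stop("degenerate labels: all compounds ",
         if (all(activity)) "active" else "inactive", call. = FALSE)
  feats <- .rule_features(flags)
  stats <- do.call(rbind, lapply(names(feats), function(nm) {
    f <- feats[[nm]]
    necessity <- mean(f[activity])
    p_given_f <- if (any(f)) mean(activity[f]) else NA_real_
    # a feature with no negative examples cannot be contradicted by the data;
    # P(active | !flag) is taken as 0 so its gap reduces to P(active | flag)
    p_given_nf <- if (any(!f)) mean(activity[!f]) else 0
    gap <- p_given_f - p_given_nf
    data.frame(flag = nm, necessity = necessity,
               p_active_given_flag = p_given_f,
               p_active_given_not_flag = p_given_nf,
               sufficiency_gap = gap, stringsAsFactors = FALSE)
  }))
  passes <- !is.na(stats$sufficiency_gap) &
    stats$necessity >= necessity_min & stats$sufficiency_gap > 0
  required <- stats$flag[passes]
  # ordinal amide handling: highest qualifying level only
  if ("amide_ge_tertiary" %in% required)
    required <- setdiff(required, "amide_ge_secondary")
  structure(list(required = required, stats = stats,
                 n = length(activity), n_active = sum(activity)),
            class = "pharmacophore_rule")
}

#' @export
print.pharmacophore_rule <- function(x, ...) {
  cat(sprintf("Pharmacophore rule (%d compounds, %d active):\n",
              x$n, x$n_active))
  if (length(x$required) == 0L) cat("  (no required features)\n")
  else cat("  required:", paste(x$required, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits CV(c) = 100 / (1 + (c / IC50)^hill) by least squares, with the top
#' asymptote fixed at 100% (vehicle control) and the bottom at 0%.
#' Initialization is multi-start over a geometric IC50 grid and several Hill
#' slopes; exact duplicate records are collapsed before fitting.
#'
#' @param cvs data.frame with `concentration_um` and `mean_cv` (>= 4
#'   concentrations).
#' @return A `dose_response_fit`: list with `ic50` (uM), `hill`,
#'   `residual_sse`, `converged`.
#' @export
fit_dose_response <- function(cvs) {
  cvs <- unique(cvs[, c("concentration_um", "mean_cv")])
  if (length(unique(cvs$concentration_um)) < 4L)
    stop("need at least 4 concentrations", call. = FALSE)
  if (any(cvs$concentration_um <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  conc <- cvs$concentration_um
  cv <- cvs$mean_cv
  sse <- function(p) {
    pred <- 100 / (1 + (conc / exp(p[1]))^exp(p[2]))
    sum((cv - pred)^2)
  }
  ic50_starts <- exp(seq(log(min(conc) / 2), log(max(conc) * 2),
                         length.out = 5))
  hill_starts <- c(0.5, 1, 1.5, 2, 4)
  best <- NULL
  for (i0 in ic50_starts) {
    for (h0 in hill_starts) {
      fit <- tryCatch(
        stats::optim(c(log(i0), log(h0)), sse, method = "Nelder-Mead",
                     control = list(maxit = 2000L, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best)) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_,
                          residual_sse = NA_real_, converged = FALSE),
                     class = "dose_response_fit"))
  }
  ic50 <- exp(best$par[1])
  hill <- exp(best$par[2])
  converged <- best$convergence == 0 && is.finite(ic50) && ic50 > 0 &&
    ic50 < max(conc) * 100
  structure(list(ic50 = ic50, hill = hill, residual_sse = best$value,
                 converged = converged),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) cat("4PL fit: not converged\n")
  else cat(sprintf("4PL fit: IC50 = %.2f uM, Hill = %.2f (SSE %.2f)\n",
                   x$ic50, x$hill, x$residual_sse))
  invisible(x)
}

#' Flags and activity for every compound of a library
#'
#' Convenience wrapper joining [substructure_flags()] (from structure) with
#' [call_activity()] (from the library's viability records) for rule
#' induction. Compounds without a record at the reference concentration are
#' dropped.
#'
#' @param lib A `bpa_library`.
#' @param threshold,concentration Passed to [call_activity()].
#' @return List with `flags` (data.frame), `activity` (logical), `id`.
#' @export
library_flags_activity <- function(lib, threshold = 50, concentration = 25) {
  comp <- lib$compounds
  keep <- vapply(comp$id, function(id) {
    any(lib$cv$compound_id == id &
          lib$cv$concentration_um == concentration)
  }, FALSE)
  ids <- comp$id[keep]
  flags <- do.call(rbind, lapply(ids, function(id) {
    f <- substructure_flags(comp$smiles[comp$id == id])
    data.frame(carbonyl_linker = f$carbonyl_linker,
               para_chloro = f$para_chloro,
               gem_dimethyl = f$gem_dimethyl,
               amide_class = f$amide_class,
               permanent_cation = f$permanent_cation,
               stringsAsFactors = FALSE)
  }))
  activity <- vapply(ids, function(id) {
    call_activity(lib$cv[lib$cv$compound_id == id, , drop = FALSE],
                  threshold, concentration)
  }, FALSE)
  list(id = ids, flags = flags, activity = unname(activity))
}
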
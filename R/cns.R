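# CNS penetrability scoring: six-component CNS-MPO desirability score,
# linear logBB blood-brain-barrier model, and threshold triage.

#' Default scoring configuration
#'
#' Reads the packaged `thresholds.yaml`: CNS-MPO desirability breakpoints for
#' the six properties (clogp, clogd, mw, tpsa, hbd, pka), the triage cutoffs
#' (MPO >= 4, MPA <= 70 A^2, logS >= -4.5, MP in 30-40 A^3, ClogP in 2-5),
#' and the logBB model coefficients with its class cutoffs (readily > 0.3,
#' poor < -1.0).
#'
#' @param path Optional path to an alternate YAML config.
#' @return Nested list with elements `mpo`, `triage`, `logbb`.
#' @export
cns_config <- function(path = NULL) {
  if (is.null(path)) path <- bpa_fixture_path("thresholds")
  cfg <- yaml::read_yaml(path)
  stopifnot(all(c("mpo", "triage", "logbb") %in% names(cfg)))
  cfg
}

#' Piecewise-linear desirability transform
#'
#' `monotone_decreasing` with breakpoints `(a, b)`: 1 at or below `a`, 0 at
#' or above `b`, linear between. `hump` with breakpoints `(a, b, c, d)`: 0
#' outside `(a, d)`, 1 on `[b, c]`, linear on the shoulders.
#'
#' @param value Numeric vector to score.
#' @param spec List with `kind` and `breakpoints` (strictly ascending).
#' @return Desirabilities in `[0, 1]`.
#' @export
desirability <- function(value, spec) {
  if (any(!is.finite(value))) stop("non-finite value", call. = FALSE)
  bp <- as.numeric(spec$breakpoints)
  if (is.unsorted(bp, strictly = TRUE))
    stop("breakpoints must be strictly ascending", call. = FALSE)
  if (identical(spec$kind, "monotone_decreasing")) {
    stopifnot(length(bp) == 2L)
    pmin(1, pmax(0, (bp[2] - value) / (bp[2] - bp[1])))
  } else if (identical(spec$kind, "hump")) {
    stopifnot(length(bp) == 4L)
    up <- pmin(1, pmax(0, (value - bp[1]) / (bp[2] - bp[1])))
    down <- pmin(1, pmax(0, (bp[4] - value) / (bp[4] - bp[3])))
    pmin(up, down)
  } else {
    stop("unknown desirability kind: ", spec$kind, call. = FALSE)
  }
}

#' CNS multiparameter optimization (CNS-MPO) score
#'
#' Unweighted sum of six desirability components (clogp, clogd, mw, tpsa,
#' hbd, pka) on a 0-6 scale. A compound with no basic center (`pka_basic`
#' `NA`) takes pKa desirability 1; a permanent cation (`pka_basic` `Inf`)
#' takes 0.
#'
#' @param panel One-row data.frame (or list) with `clogp`, `clogd`, `mw`,
#'   `psa` (or `tpsa`), `hbd`, `pka_basic`.
#' @param config Scoring configuration from [cns_config()].
#' @return An `mpo_score`: list with `components` (named, each in `[0, 1]`)
#'   and `total` in `[0, 6]`.
#' @export
cns_mpo <- function(panel, config = cns_config()) {
  need <- c("clogp", "clogd", "mw", "hbd")
  tpsa <- panel$psa %||% panel$tpsa
  if (is.null(tpsa)) stop("missing descriptor: psa", call. = FALSE)
  for (nm in need) {
    if (is.null(panel[[nm]]) || is.na(panel[[nm]]))
      stop("missing descriptor: ", nm, call. = FALSE)
  }
  if (!"pka_basic" %in% names(panel))
    stop("missing descriptor: pka_basic", call. = FALSE)
  pka <- panel$pka_basic
  pka_component <- if (is.na(pka)) 1
                   else if (is.infinite(pka)) 0
                   else desirability(pka, config$mpo$pka)
  comps <- c(
    clogp = desirability(panel$clogp, config$mpo$clogp),
    clogd = desirability(panel$clogd, config$mpo$clogd),
    mw = desirability(panel$mw, config$mpo$mw),
    tpsa = desirability(tpsa, config$mpo$tpsa),
    hbd = desirability(panel$hbd, config$mpo$hbd),
    pka = pka_component
  )
  structure(list(components = comps, total = sum(comps)),
            class = "mpo_score")
}

#' @export
print.mpo_score <- function(x, ...) {
  cat(sprintf("CNS-MPO %.2f / 6  [%s]\n", x$total,
              paste(sprintf("%s %.2f", names(x$components), x$components),
                    collapse = ", ")))
  invisible(x)
}

#' Linear logBB blood-brain-barrier model
#'
#' Estimated log10 brain-to-plasma concentration ratio:
#' logBB = 0.152 ClogP - 0.0148 PSA + 0.139.
#'
#' @param clogp Calculated logP.
#' @param psa Polar surface area, square Angstroms.
#' @param config Scoring configuration (holds the coefficients).
#' @return logBB estimate.
#' @examples
#' compute_logbb(0, 0)  # the intercept, 0.139
#' @export
compute_logbb <- function(clogp, psa, config = cns_config()) {
  stopifnot(is.finite(clogp), is.finite(psa))
  cf <- config$logbb
  cf$coef_clogp * clogp + cf$coef_psa * psa + cf$intercept
}

#' Classify blood-brain-barrier penetration from logBB
#'
#' logBB above 0.3 indicates ready BBB crossing; below -1.0, poor brain
#' distribution; between the cutoffs, intermediate penetration.
#'
#' @param logbb Numeric vector of logBB values.
#' @param config Scoring configuration (holds the cutoffs).
#' @return Factor with levels `readily_crosses`, `intermediate`, `poor`.
#' @export
classify_bbb <- function(logbb, config = cns_config()) {
  stopifnot(all(is.finite(logbb)))
  cf <- config$logbb
  cls <- ifelse(logbb > cf$readily_cutoff, "readily_crosses",
                ifelse(logbb < cf$poor_cutoff, "poor", "intermediate"))
  factor(cls, levels = c("readily_crosses", "intermediate", "poor"))
}

#' Apply the triage criteria to one compound
#'
#' Per-criterion pass/fail flags: CNS-MPO >= 4, MPA <= 70 A^2,
#' logS >= -4.5, MP in 30-40 A^3, ClogP in 2-5, plus the logBB class. The
#' rank score counts passed criteria (a `readily_crosses` logBB class counts
#' as a pass).
#'
#' @param panel One-row descriptor panel (needs `mpa`, `logs`, `mp`,
#'   `clogp`).
#' @param mpo An `mpo_score` for the same compound.
#' @param bbb Optional precomputed logBB value (computed from the panel when
#'   `NULL`).
#' @param config Scoring configuration.
#' @return List with `flags` (named logicals), `logbb_class`, `mpo_total`,
#'   `logbb`, `rank_score`.
#' @export
apply_triage <- function(panel, mpo, bbb = NULL, config = cns_config()) {
  tr <- config$triage
  if (is.null(bbb)) bbb <- compute_logbb(panel$clogp,
                                         panel$psa %||% panel$tpsa,
                                         config)
  cls <- classify_bbb(bbb, config)
  flags <- c(
    mpo_ge_4 = mpo$total >= tr$mpo_min,
    logbb_readily = cls == "readily_crosses",
    mpa_le_70 = !is.na(panel$mpa) && panel$mpa <= tr$mpa_max,
    logs_ge_minus4_5 = panel$logs >= tr$logs_min,
    mp_in_30_40 = panel$mp >= tr$mp_range[1] && panel$mp <= tr$mp_range[2],
    clogp_in_2_5 = panel$clogp >= tr$clogp_range[1] &&
      panel$clogp <= tr$clogp_range[2]
  )
  list(flags = flags, logbb_class = cls, mpo_total = mpo$total,
       logbb = bbb, rank_score = sum(flags))
}

#' Score and triage a profiled library
#'
#' Computes the CNS-MPO score, logBB and triage flags for every row of a
#' descriptor table and returns them ranked: by criteria passed, ties broken
#' by MPO total (descending), then logBB (descending), then id.
#'
#' @param panels data.frame from [profile_library()] (column `id` + panel
#'   columns).
#' @param config Scoring configuration.
#' @return data.frame with scores, class, per-criterion flags and `rank`.
#' @export
triage_library <- function(panels, config = cns_config()) {
  rows <- lapply(seq_len(nrow(panels)), function(i) {
    p <- panels[i, ]
    mpo <- cns_mpo(p, config)
    tr <- apply_triage(p, mpo, config = config)
    data.frame(id = p$id, mpo = mpo$total, logbb = tr$logbb,
               logbb_class = as.character(tr$logbb_class),
               t(as.data.frame(tr$flags)),
               n_pass = tr$rank_score, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$n_pass, -out$mpo, -out$logbb, out$id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
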
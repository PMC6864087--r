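#' Path to a packaged fixture file
#'
#' @param which One of `"compounds"`, `"viability"`, `"reference"`,
#'   `"thresholds"`.
#' @return Absolute path to the installed file.
#' @export
bpa_fixture_path <- function(which = c("compounds", "viability", "reference",
                                       "thresholds")) {
  which <- match.arg(which)
  fname <- switch(which,
    compounds = "bpa_compounds.csv",
    viability = "bpa_viability.csv",
    reference = "reference_values.csv",
    thresholds = "thresholds.yaml")
  system.file("extdata", fname, package = "bpatriage", mustWork = TRUE)
}

.region_levels <- list(
  region_a = c("Cl", "F", "H", "Br", "other"),
  region_b = c("carbonyl", "methylene", "ether", "reduced-ring"),
  region_c = c("gem-dimethyl", "monomethyl", "unsubstituted")
)

#' Load a compound library table
#'
#' Reads a comma-delimited, UTF-8 library table with header row and columns
#' `id`, `name`, `smiles`, `region_a`, `region_b`, `region_c`, `region_d`,
#' and optionally `salt` and `synonyms`. Lines starting with `#` are
#' comments. Cell-viability records can be supplied either in a second file
#' (`cv_path`, columns `compound_id`, `concentration_um`, `mean_cv`,
#' `sd_cv`) or as those same optional columns appended to the main table.
#'
#' All invariants are checked on load: unique ids, parseable SMILES, CV rows
#' referencing known compounds, positive concentrations, non-negative SDs.
#'
#' @param path Path to the compound CSV.
#' @param cv_path Optional path to a viability CSV.
#' @return A `bpa_library`: list with data frames `compounds` and `cv`.
#' @examples
#' lib <- load_library(bpa_fixture_path("compounds"),
#'                     bpa_fixture_path("viability"))
#' nrow(lib$compounds)
#' @export
load_library <- function(path, cv_path = NULL) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("id", "name", "smiles", "region_a", "region_b", "region_c",
            "region_d")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("library table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"salt" %in% names(tab)) tab$salt <- "none"
  if (!"synonyms" %in% names(tab)) tab$synonyms <- ""
  tab$salt[is.na(tab$salt) | tab$salt == ""] <- "none"

  cv_cols <- c("concentration_um", "mean_cv", "sd_cv")
  inline_cv <- all(cv_cols %in% names(tab))
  compounds <- tab[!duplicated(tab$id), c(need, "salt", "synonyms")]
  rownames(compounds) <- NULL

  if (anyDuplicated(compounds$id))
    stop("duplicate compound id: ",
         compounds$id[duplicated(compounds$id)][1], call. = FALSE)
  dup_struct <- tab$id[duplicated(tab$id) &
                         !is.na(tab$smiles) & tab$smiles != ""]
  if (!inline_cv && anyDuplicated(tab$id))
    stop("duplicate compound id: ", tab$id[duplicated(tab$id)][1],
         call. = FALSE)

  cv <- data.frame(compound_id = character(0), concentration_um = numeric(0),
                   mean_cv = numeric(0), sd_cv = numeric(0))
  if (inline_cv) {
    rows <- !is.na(tab$concentration_um)
    cv <- data.frame(compound_id = tab$id[rows],
                     concentration_um = as.numeric(tab$concentration_um[rows]),
                     mean_cv = as.numeric(tab$mean_cv[rows]),
                     sd_cv = as.numeric(tab$sd_cv[rows]))
  }
  if (!is.null(cv_path)) {
    cvt <- utils::read.csv(cv_path, comment.char = "#",
                           stringsAsFactors = FALSE)
    need_cv <- c("compound_id", "concentration_um", "mean_cv")
    if (!all(need_cv %in% names(cvt)))
      stop("viability table lacks column(s): ",
           paste(setdiff(need_cv, names(cvt)), collapse = ", "),
           call. = FALSE)
    if (!"sd_cv" %in% names(cvt)) cvt$sd_cv <- NA_real_
    cv <- rbind(cv, cvt[, c("compound_id", "concentration_um", "mean_cv",
                            "sd_cv")])
  }

  unknown <- setdiff(cv$compound_id, compounds$id)
  if (length(unknown) > 0L)
    stop("viability row references unknown compound id: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  if (any(!is.na(cv$concentration_um) & cv$concentration_um <= 0))
    stop("viability concentration must be > 0", call. = FALSE)
  if (any(!is.na(cv$sd_cv) & cv$sd_cv < 0))
    stop("negative viability SD", call. = FALSE)

  # every SMILES must parse
  for (i in seq_len(nrow(compounds))) {
    tryCatch(parse_structure(compounds$smiles[i]),
             error = function(e) stop("compound ", compounds$id[i],
                                      ": ", conditionMessage(e),
                                      call. = FALSE))
  }

  structure(list(compounds = compounds, cv = cv), class = "bpa_library")
}

#' @export
print.bpa_library <- function(x, ...) {
  cat(sprintf("<bpa_library> %d compounds, %d viability records\n",
              nrow(x$compounds), nrow(x$cv)))
  invisible(x)
}

#' The packaged BPA fixture library
#'
#' Convenience wrapper loading the packaged compound structures together with
#' the transcribed cell-viability records.
#'
#' @return A `bpa_library`.
#' @export
bpa_fixture_library <- function() {
  load_library(bpa_fixture_path("compounds"), bpa_fixture_path("viability"))
}

#' Printed reference descriptor values
#'
#' Long-format table of vendor-computed descriptor values printed in the
#' source tables (ClogP, PSA, MP, MPO, logBB, logS by compound id). These are
#' inputs for worked examples; the package's open contribution schemes are
#' not expected to reproduce the vendor ClogP/LogS/pKa values.
#'
#' @return data.frame with columns `id`, `property`, `value`.
#' @export
reference_values <- function() {
  utils::read.csv(bpa_fixture_path("reference"), comment.char = "#",
                  stringsAsFactors = FALSE)
}

# ---- Enumeration ------------------------------------------------------------

# Fragment vocabularies for the four modification regions of the BPA
# scaffold. Region D fragments are written N-first so that appending them
# after the amide carbonyl bonds the nitrogen to it.
.bpa_region_choices <- function() {
  list(
    A = c(Cl = "Cl", F = "F", H = "", Br = "Br"),
    B = c(carbonyl = "C(=O)", methylene = "C", ether = "O",
          `reduced-ring` = "reduced"),
    C = c(`gem-dimethyl` = "C(C)(C)", monomethyl = "C(C)",
          unsubstituted = "C"),
    D = c(`acid` = "O",
          `ester-isopropyl` = "OC(C)C",
          `primary` = "N",
          `sec-N-methyl` = "NC",
          `sec-N-hydroxyethyl` = "NCCO",
          `sec-N-ethyl` = "NCC",
          `sec-N-diethylaminoethyl` = "NCCN(CC)CC",
          `tert-NN-dimethyl` = "N(C)C",
          `tert-N-methyl-N-hydroxyethyl` = "N(C)CCO",
          `tert-NN-bis-hydroxyethyl` = "N(CCO)CCO",
          `tert-N-methyl-N-ethyl` = "N(C)CC",
          `tert-N-methylpiperazine` = "N1CCN(C)CC1",
          `tert-NN-dimethylpiperazinium` = "N1CC[N+](C)(C)CC1")
  )
}

.assemble_bpa_smiles <- function(a, b, c_frag, d) {
  choices <- .bpa_region_choices()
  asub <- choices$A[[a]]
  ring <- if (asub == "") "c2ccccc2" else paste0("c2ccc(", asub, ")cc2")
  bfrag <- choices$B[[b]]
  linker <- if (bfrag == "reduced") {
    satring <- if (asub == "") "C2CCCCC2" else paste0("C2CCC(", asub, ")CC2")
    paste0("C", satring)
  } else {
    paste0(bfrag, ring)
  }
  calpha <- choices$C[[c_frag]]
  dfrag <- choices$D[[d]]
  paste0(calpha, "(Oc1ccc(", linker, ")cc1)C(=O)", dfrag)
}

#' Enumerate BPA variants over a region grid
#'
#' Builds one compound per element of the Cartesian product of per-region
#' choices on the fixed BPA template: an aryloxy(alpha-carbon) acid amide
#' with region A = para substituent of the distal ring, region B = linker
#' between the rings, region C = alpha substitution, region D = the amide
#' nitrogen moiety. All generated SMILES are parsed and canonicalized;
#' duplicates (by canonical form) are removed, ties broken by lexicographic
#' SMILES, and the output ordering is deterministic.
#'
#' @param options Named list with elements `A`, `B`, `C`, `D`, each a
#'   character vector of choice labels (see [bpa_region_options()] for the
#'   available labels).
#' @return data.frame with columns `id`, `smiles`, `canonical`, `region_a`,
#'   `region_b`, `region_c`, `region_d`.
#' @examples
#' v <- enumerate_bpa_variants(list(A = c("Cl", "F"), B = "carbonyl",
#'                                  C = "gem-dimethyl",
#'                                  D = "tert-N-methyl-N-hydroxyethyl"))
#' nrow(v)  # 2
#' @export
enumerate_bpa_variants <- function(options) {
  choices <- .bpa_region_choices()
  for (r in c("A", "B", "C", "D")) {
    if (is.null(options[[r]]) || length(options[[r]]) == 0L)
      stop("region ", r, " needs at least one choice", call. = FALSE)
    bad <- setdiff(options[[r]], names(choices[[r]]))
    if (length(bad) > 0L)
      stop("region ", r, ": unknown choice(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(options[[r]]))
      stop("region ", r, ": duplicated choice", call. = FALSE)
  }
  grid <- expand.grid(A = options$A, B = options$B, C = options$C,
                      D = options$D, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  smiles <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    smi <- .assemble_bpa_smiles(grid$A[i], grid$B[i], grid$C[i], grid$D[i])
    tryCatch(parse_structure(smi),
             error = function(e)
               stop(sprintf("invalid fragment combination (A=%s, B=%s, C=%s, D=%s): %s",
                            grid$A[i], grid$B[i], grid$C[i], grid$D[i],
                            conditionMessage(e)), call. = FALSE))
    smiles[i] <- smi
  }
  canon <- canonical_smiles(smiles)
  out <- data.frame(
    id = sprintf("V%03d", seq_len(nrow(grid))),
    smiles = smiles,
    canonical = canon,
    region_a = grid$A, region_b = grid$B, region_c = grid$C,
    region_d = grid$D,
    stringsAsFactors = FALSE
  )
  # deduplicate on canonical form; ties broken by lexicographic SMILES
  out <- out[order(out$canonical, out$smiles), , drop = FALSE]
  out <- out[!duplicated(out$canonical), , drop = FALSE]
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Available region choice labels for the BPA enumerator
#'
#' @return Named list of character vectors (regions A-D).
#' @export
bpa_region_options <- function() {
  lapply(.bpa_region_choices(), names)
}
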
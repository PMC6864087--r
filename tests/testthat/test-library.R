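test_that("the packaged fixture loads with the named compounds and CV rows", {
  lib <- bpa_fixture_library()
  expect_true(all(c("FF", "FFA", "AA", "MA", "DMA", "HR1", "HR2", "HR5",
                    "HR32", "HR35", "HR36", "PP1") %in% lib$compounds$id))
  # PP1 carries the HR40 synonym used interchangeably in the series
  expect_equal(lib$compounds$synonyms[lib$compounds$id == "PP1"], "HR40")
  pp1 <- lib$cv[lib$cv$compound_id == "PP1", ]
  expect_true(any(pp1$concentration_um == 10 & pp1$mean_cv == 43.67 &
                    pp1$sd_cv == 1.88))
  expect_true(any(pp1$concentration_um == 5 & pp1$mean_cv == 70.03 &
                    pp1$sd_cv == 2.04))
})

test_that("library loading enforces its invariants", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  header <- "id,name,smiles,region_a,region_b,region_c,region_d"
  row <- "X1,x,CCO,Cl,carbonyl,gem-dimethyl,primary"
  writeLines(c(header, row, row), tmp)
  expect_error(load_library(tmp), "duplicate compound id")

  writeLines(c(header, row), tmp)
  lib <- load_library(tmp)
  expect_equal(nrow(lib$cv), 0L)  # no CV columns -> zero records

  cvf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,concentration_um,mean_cv,sd_cv",
               "X9,25,50,1"), cvf)
  expect_error(load_library(tmp, cvf), "unknown compound id")
  writeLines(c("compound_id,concentration_um,mean_cv,sd_cv",
               "X1,25,50,-1"), cvf)
  expect_error(load_library(tmp, cvf), "negative")
  writeLines(c(header, "X1,x,C1CC,Cl,carbonyl,gem-dimethyl,primary"), tmp)
  expect_error(load_library(tmp), "parse error")
})

test_that("enumeration count equals the product of per-region options", {
  opts <- list(A = c("Cl", "F"), B = c("carbonyl", "methylene", "ether"),
               C = c("gem-dimethyl", "monomethyl", "unsubstituted"),
               D = c("primary", "sec-N-methyl", "tert-NN-dimethyl",
                     "tert-N-methyl-N-hydroxyethyl"))
  v <- enumerate_bpa_variants(opts)
  expect_equal(nrow(v), 2L * 3L * 3L * 4L)
  expect_equal(anyDuplicated(v$canonical), 0L)
})

test_that("the PP1 single-choice enumeration reproduces the fixture SMILES", {
  v <- enumerate_bpa_variants(list(A = "Cl", B = "carbonyl",
                                   C = "gem-dimethyl",
                                   D = "tert-N-methyl-N-hydroxyethyl"))
  expect_equal(nrow(v), 1L)
  expect_equal(v$canonical, canonical_smiles(PP1_SMILES))
})

test_that("enumeration rejects unknown or empty region choices", {
  expect_error(enumerate_bpa_variants(list(A = "Cl", B = "carbonyl",
                                           C = "gem-dimethyl",
                                           D = "no-such-fragment")),
               "region D")
  expect_error(enumerate_bpa_variants(list(A = character(0), B = "carbonyl",
                                           C = "gem-dimethyl",
                                           D = "primary")),
               "region A")
})

test_that("fixture region tags agree with structure-derived flags", {
  lib <- bpa_fixture_library()
  for (i in seq_len(nrow(lib$compounds))) {
    row <- lib$compounds[i, ]
    fl <- substructure_flags(row$smiles)
    expect_equal(fl$carbonyl_linker, row$region_b == "carbonyl",
                 info = row$id)
    expect_equal(fl$para_chloro, row$region_a == "Cl", info = row$id)
    expect_equal(fl$gem_dimethyl, row$region_c == "gem-dimethyl",
                 info = row$id)
    expected_class <- if (row$id == "FF") "ester"
      else if (row$id == "FFA") "acid"
      else if (startsWith(row$region_d, "tert-")) "tertiary"
      else if (startsWith(row$region_d, "sec-")) "secondary"
      else "primary"
    expect_equal(fl$amide_class, expected_class, info = row$id)
    expect_equal(fl$permanent_cation, row$id == "HR36", info = row$id)
  }
})
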
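test_that("pharmacophore flags match the fixture structures", {
  pp1 <- substructure_flags(PP1_SMILES)
  expect_true(pp1$carbonyl_linker)
  expect_true(pp1$para_chloro)
  expect_true(pp1$gem_dimethyl)
  expect_equal(pp1$amide_class, "tertiary")
  expect_false(pp1$permanent_cation)
  # HR2: carbonyl reduced to methylene
  hr2 <- substructure_flags(
    "OCCN(C)C(=O)C(C)(C)Oc1ccc(Cc2ccc(Cl)cc2)cc1")
  expect_false(hr2$carbonyl_linker)
  expect_true(hr2$para_chloro)
  hr36 <- substructure_flags(HR36_SMILES)
  expect_true(hr36$permanent_cation)
  # absent scaffold: all structural flags off, class from the acyl group
  plain <- substructure_flags("CCO")
  expect_false(plain$carbonyl_linker)
  expect_false(plain$para_chloro)
  expect_equal(plain$amide_class, "none")
})

test_that("activity calls use the reference concentration and threshold", {
  pp1 <- data.frame(concentration_um = 25, mean_cv = 1.04)
  expect_true(call_activity(pp1))
  hr36 <- data.frame(concentration_um = 25, mean_cv = 98)
  expect_false(call_activity(hr36))
  boundary <- data.frame(concentration_um = 25, mean_cv = 50)
  expect_true(call_activity(boundary))            # <= convention
  expect_error(call_activity(data.frame(concentration_um = 10,
                                        mean_cv = 40)), "25")
  expect_true(call_activity(data.frame(concentration_um = 10,
                                       mean_cv = 40), concentration = 10))
  # monotone: lowering CV never flips active -> inactive
  for (cv in seq(0, 100, by = 10)) {
    a_hi <- call_activity(data.frame(concentration_um = 25, mean_cv = cv))
    a_lo <- call_activity(data.frame(concentration_um = 25,
                                     mean_cv = cv - 5))
    expect_true(a_lo >= a_hi)
  }
})

test_that("matched pairs differ in exactly the named region", {
  v <- enumerate_bpa_variants(list(A = c("Cl", "F"), B = "carbonyl",
                                   C = "gem-dimethyl",
                                   D = "tert-N-methyl-N-hydroxyethyl"))
  lib <- structure(list(
    compounds = data.frame(id = v$id, name = "", smiles = v$smiles,
                           region_a = v$region_a, region_b = v$region_b,
                           region_c = v$region_c, region_d = v$region_d,
                           salt = "none", synonyms = ""),
    cv = data.frame(compound_id = character(0),
                    concentration_um = numeric(0), mean_cv = numeric(0),
                    sd_cv = numeric(0))), class = "bpa_library")
  pairs_a <- matched_pairs(lib, "A")
  expect_equal(nrow(pairs_a), 1L)          # 2 x 1 x 1 x 1 grid
  expect_equal(nrow(matched_pairs(lib, "B")), 0L)
  # ids ordered lexicographically
  expect_true(pairs_a$id_a < pairs_a$id_b)
})

test_that("the fixture PP1/HR9 fluoro swap is a region-A matched pair", {
  lib <- bpa_fixture_library()
  pairs_a <- matched_pairs(lib, "A")
  row <- pairs_a[pairs_a$id_a == "HR9" & pairs_a$id_b == "PP1", ]
  expect_equal(nrow(row), 1L)
  # CV(PP1) - CV(HR9) at 25 uM: 1.04 - 35.55
  expect_equal(row$delta_cv, 1.04 - 35.55, tolerance = 1e-9)
  # HR2 (methylene) and PP1 (carbonyl) differ in region B only
  pairs_b <- matched_pairs(lib, "B")
  expect_true(any(pairs_b$id_a == "HR2" & pairs_b$id_b == "PP1"))
  # pairs differing in two regions are excluded: HR2 vs HR9 differ in A and B
  expect_false(any((pairs_a$id_a == "HR2" & pairs_a$id_b == "HR9") |
                     (pairs_b$id_a == "HR2" & pairs_b$id_b == "HR9")))
})

test_that("rule induction recovers a planted rule exactly at zero noise", {
  spec <- synthetic_library_spec(noise_sd = 0, seed = 4)
  lib <- generate_virtual_library(spec)
  fa <- library_flags_activity(lib)
  rule <- induce_rule(fa$flags, fa$activity)
  expect_setequal(rule$required, spec$planted_rule)
})

test_that("rule induction rejects degenerate input", {
  flags <- data.frame(carbonyl_linker = rep(TRUE, 12),
                      para_chloro = TRUE, gem_dimethyl = TRUE,
                      amide_class = "tertiary", permanent_cation = FALSE)
  expect_error(induce_rule(flags, rep(TRUE, 12)), "degenerate")
  expect_error(induce_rule(flags, rep(FALSE, 12)), "degenerate")
  expect_error(induce_rule(flags[1:5, ], rep(c(TRUE, FALSE), c(2, 3))),
               "at least 10")
})

test_that("fixture rule induction flags the carbonyl linker and gem-dimethyl", {
  # Only six fixture compounds carry a transcribed 25 uM viability value, so
  # the minimum-n precondition is relaxed for this small regression check.
  lib <- bpa_fixture_library()
  fa <- library_flags_activity(lib)
  rule <- induce_rule(fa$flags, fa$activity, min_n = 5L)
  expect_true(all(c("carbonyl_linker", "gem_dimethyl") %in% rule$required))
  # the 4'-chloro requirement is not recoverable from this small transcribed
  # subset: the fluoro analog HR9 is itself moderately active at 25 uM, which
  # caps para_chloro necessity at 2/3 (the same exception the series' own
  # halogen comparison highlights)
  pc <- rule$stats[rule$stats$flag == "para_chloro", ]
  expect_equal(pc$necessity, 2 / 3, tolerance = 1e-9)
  expect_false("para_chloro" %in% rule$required)
})

test_that("the 4PL fit recovers exact data and the printed PP1 series", {
  conc <- c(1, 3, 10, 30, 100)
  exact <- data.frame(concentration_um = conc,
                      mean_cv = 100 / (1 + (conc / 10)^1.5))
  fit <- fit_dose_response(exact)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 10, tolerance = 1e-4)
  expect_equal(fit$hill, 1.5, tolerance = 1e-4)

  pp1 <- data.frame(concentration_um = c(1, 5, 10, 25),
                    mean_cv = c(98.36, 70.03, 43.67, 1.04))
  fit_pp1 <- fit_dose_response(pp1)
  expect_true(fit_pp1$converged)
  expect_gte(fit_pp1$ic50, 8)
  expect_lte(fit_pp1$ic50, 11)
})

test_that("the 4PL fit ignores duplicates and is scale-equivariant", {
  conc <- c(1, 3, 10, 30, 100)
  d <- data.frame(concentration_um = conc,
                  mean_cv = 100 / (1 + (conc / 7)^2) + c(1, -2, 2, -1, 0))
  base <- fit_dose_response(d)
  dup <- rbind(d, d[2, ], d[4, ])
  fit_dup <- fit_dose_response(dup)
  expect_equal(fit_dup$ic50, base$ic50, tolerance = 1e-8)
  scaled <- d
  scaled$concentration_um <- d$concentration_um * 3
  fit_scaled <- fit_dose_response(scaled)
  expect_equal(fit_scaled$ic50, base$ic50 * 3, tolerance = 1e-4)
  expect_equal(fit_scaled$hill, base$hill, tolerance = 1e-4)
  expect_error(fit_dose_response(d[1:3, ]), "4 concentrations")
})
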
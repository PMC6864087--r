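test_that("TPSA reproduces the printed values for PP1 and HR1 exactly", {
  expect_identical(compute_tpsa(PP1_SMILES), 66.84)
  expect_identical(compute_tpsa(HR1_SMILES), 49.77)
})

test_that("TPSA fragment sums match hand-computed cases", {
  expect_identical(compute_tpsa("OCCNCCO"), 52.49)  # 12.03 + 2 * 20.23
  expect_identical(compute_tpsa("CCCCCC"), 0)       # pure hydrocarbon
  expect_identical(compute_tpsa("c1ccccc1CCC"), 0)
  # counterions stripped; quaternary N+ contributes 0.00
  expect_identical(compute_tpsa(HR36_SMILES), 46.61)
})

test_that("TPSA is invariant to how the same molecule is written", {
  forms <- c(PP1_SMILES,
             "Clc1ccc(cc1)C(=O)c1ccc(OC(C)(C)C(=O)N(C)CCO)cc1",
             "C(CO)N(C)C(=O)C(C)(C)Oc1ccc(cc1)C(=O)c1ccc(Cl)cc1")
  vals <- vapply(forms, compute_tpsa, 0)
  expect_true(all(vals == vals[1]))
})

test_that("ClogP atom contributions match hand sums on small molecules", {
  expect_equal(compute_clogp("C"), 0.1441 + 4 * 0.1230, tolerance = 1e-12)
  expect_equal(compute_clogp("c1ccccc1"), 6 * (0.1581 + 0.1230),
               tolerance = 1e-12)
  # adding a CH2 to an alkane increases the estimate
  expect_gt(compute_clogp("CC"), compute_clogp("C"))
  expect_gt(compute_clogp("CCC"), compute_clogp("CC"))
})

test_that("polarizability is an additive atomic-hybrid sum", {
  expect_equal(compute_polarizability("C"), 2.609, tolerance = 1e-12)
  expect_equal(compute_polarizability("O"), 1.411, tolerance = 1e-12)
  # CH2 homologation adds a constant increment
  incr <- diff(vapply(c("CC", "CCC", "CCCC", "CCCCC"),
                      compute_polarizability, 0))
  expect_true(all(abs(incr - incr[1]) < 1e-12))
  # swapping para-Cl for para-F changes the sum by exactly alpha(Cl)-alpha(F)
  hr9 <- "OCCN(C)C(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(F)cc2)cc1"
  expect_equal(compute_polarizability(PP1_SMILES) -
                 compute_polarizability(hr9),
               2.315 - 0.296, tolerance = 1e-12)
})

test_that("the solubility model evaluates the published linear form", {
  expect_equal(compute_logs(2, 300, 4, 0.5), -3.066 + log10(300),
               tolerance = 1e-12)
  # strictly decreasing in clogp
  vals <- vapply(seq(0, 5, by = 0.5), function(cp)
    compute_logs(cp, 300, 4, 0.5), 0)
  expect_true(all(diff(vals) < 0))
  expect_error(compute_logs(2, 0, 4, 0.5), "mw")
  expect_error(compute_logs(2, -10, 4, 0.5), "mw")
})

test_that("basic pKa lookup distinguishes the series' amine environments", {
  expect_true(is.na(estimate_pka_basic(PP1_SMILES)))     # amide N non-basic
  hr32 <- "CCN(CC)CCNC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1"
  expect_equal(estimate_pka_basic(hr32), 9.5)
  expect_true(is.infinite(estimate_pka_basic(HR36_SMILES)))
  hr34 <- "CN1CCN(CC1)C(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1"
  expect_equal(estimate_pka_basic(hr34), 7.8)
  expect_equal(estimate_pka_basic("CCN(CC)CC"), 9.8)     # plain tertiary
  expect_equal(estimate_pka_basic("CCNCC"), 10.8)
  expect_equal(estimate_pka_basic("CCN"), 10.6)
  expect_equal(estimate_pka_basic("Nc1ccccc1"), 4.6)     # aniline
})

test_that("clogD follows the monoprotic closed form and never exceeds clogP", {
  expect_identical(compute_clogd(2.5, NA_real_), 2.5)
  expect_equal(compute_clogd(2.5, 7.4), 2.5 - log10(2), tolerance = 1e-12)
  expect_equal(compute_clogd(0, 9.4), -2.004321, tolerance = 1e-6)
  expect_identical(compute_clogd(1, Inf), -3)  # capped permanent-cation rule
  for (cp in c(-1, 0, 2, 5)) {
    for (pk in c(NA, 5, 7.4, 9, 11, Inf)) {
      expect_lte(compute_clogd(cp, pk), cp)
    }
  }
})

test_that("H-bond counts follow the pH-7 microspecies convention", {
  expect_equal(unname(count_hbd_hba("O")), c(2L, 1L))
  expect_equal(unname(count_hbd_hba("c1ccccc1")), c(0L, 0L))
  # PP1 neutral: OH donor; ether + ketone + amide + hydroxyl O acceptors
  expect_equal(unname(count_hbd_hba(PP1_SMILES)), c(1L, 4L))
  # basic amine with pKa > 7 is protonated: one more donor, one less acceptor
  hr32 <- "CCN(CC)CCNC(=O)C(C)(C)Oc1ccc(C(=O)c2ccc(Cl)cc2)cc1"
  expect_equal(unname(count_hbd_hba(hr32)), c(2L, 3L))
  expect_equal(unname(count_hbd_hba(hr32, pH = 12)), c(1L, 4L))
})

test_that("TPSA equals the label-driven hand-sum oracle on enumerated variants", {
  opts <- list(A = c("Cl", "F"), B = c("carbonyl", "methylene"),
               C = c("gem-dimethyl"),
               D = c("primary", "sec-N-hydroxyethyl", "tert-NN-dimethyl",
                     "tert-NN-bis-hydroxyethyl", "tert-N-methylpiperazine"))
  v <- enumerate_bpa_variants(opts)
  expect_gte(nrow(v), 20L)
  for (i in seq_len(nrow(v))) {
    expect_identical(compute_tpsa(v$smiles[i]),
                     oracle_tpsa_variant(v$region_b[i], v$region_d[i]),
                     info = paste(v$region_b[i], v$region_d[i]))
  }
})

test_that("the full panel assembles with consistent fields", {
  p <- descriptor_panel(PP1_SMILES, include_mpa = FALSE)
  expect_equal(p$psa, 66.84)
  expect_gt(p$mw, 375)
  expect_lt(p$mw, 376)
  expect_true(is.na(p$pka_basic))
  expect_identical(p$clogd, p$clogp)
  expect_equal(format_pka(p$pka_basic), "none")
  expect_equal(format_pka(Inf), "permanent_cation")
})
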
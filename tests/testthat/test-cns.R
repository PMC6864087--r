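cfg <- cns_config()

test_that("desirability transforms are the stated piecewise-linear forms", {
  mono <- list(kind = "monotone_decreasing", breakpoints = c(3, 5))
  expect_equal(desirability(2, mono), 1)
  expect_equal(desirability(3, mono), 1)
  expect_equal(desirability(4, mono), 0.5)   # ramp midpoint
  expect_equal(desirability(5, mono), 0)
  expect_equal(desirability(7, mono), 0)
  hump <- list(kind = "hump", breakpoints = c(20, 40, 90, 120))
  expect_equal(desirability(150, hump), 0)
  expect_equal(desirability(10, hump), 0)
  expect_equal(desirability(30, hump), 0.5)
  expect_equal(desirability(70, hump), 1)
  expect_equal(desirability(105, hump), 0.5)
  expect_error(desirability(NaN, mono), "non-finite")
  expect_error(desirability(1, list(kind = "hump",
                                    breakpoints = c(4, 3, 2, 1))),
               "ascending")
})

test_that("CNS-MPO spans exactly 0 to 6 with the documented conventions", {
  ideal <- make_panel(clogp = 2, clogd = 1, mw = 300, psa = 70, hbd = 0,
                      pka = 7)
  expect_equal(cns_mpo(ideal, cfg)$total, 6)
  worst <- make_panel(clogp = 6, clogd = 5, mw = 600, psa = 150, hbd = 5,
                      pka = 11)
  expect_equal(cns_mpo(worst, cfg)$total, 0)
  mid <- make_panel(clogp = 4, clogd = 3, mw = 430, psa = 30, hbd = 2,
                    pka = 9)
  expect_equal(cns_mpo(mid, cfg)$total, 3)
  # pKa conventions: none -> 1, permanent cation -> 0
  expect_equal(cns_mpo(make_panel(pka = NA), cfg)$components[["pka"]], 1)
  expect_equal(cns_mpo(make_panel(pka = Inf), cfg)$components[["pka"]], 0)
  expect_error(cns_mpo(make_panel(clogp = NA), cfg), "clogp")
})

test_that("the logBB equation is exactly linear with the printed coefficients", {
  expect_identical(compute_logbb(0, 0, cfg), 0.139)
  expect_equal(compute_logbb(2, 50, cfg), -0.297, tolerance = 1e-12)
  # finite-difference slopes recover the coefficients to machine precision
  s_clogp <- (compute_logbb(1, 10, cfg) - compute_logbb(0, 10, cfg))
  s_psa <- (compute_logbb(1, 11, cfg) - compute_logbb(1, 10, cfg))
  expect_equal(s_clogp, 0.152, tolerance = 1e-14)
  expect_equal(s_psa, -0.0148, tolerance = 1e-14)
})

test_that("BBB classification partitions the line at 0.3 and -1.0", {
  expect_equal(as.character(classify_bbb(0.5, cfg)), "readily_crosses")
  expect_equal(as.character(classify_bbb(-1.5, cfg)), "poor")
  expect_equal(as.character(classify_bbb(0, cfg)), "intermediate")
  # boundary values fall in the middle class; exactly one class per value
  for (x in c(-2, -1.0, -0.999, 0.3, 0.301, 1)) {
    expect_false(is.na(classify_bbb(x, cfg)))
  }
  expect_equal(as.character(classify_bbb(0.3, cfg)), "intermediate")
  expect_equal(as.character(classify_bbb(-1.0, cfg)), "intermediate")
})

test_that("triage flags follow the published criteria", {
  p <- make_panel(mpa = 75)
  tr <- apply_triage(p, cns_mpo(p, cfg), config = cfg)
  expect_false(tr$flags[["mpa_le_70"]])
  p2 <- make_panel(mp = 35, mpa = 50)
  tr2 <- apply_triage(p2, cns_mpo(p2, cfg), config = cfg)
  expect_true(tr2$flags[["mp_in_30_40"]])
  expect_true(tr2$flags[["mpa_le_70"]])
  # HR36: printed ClogP with computed cation PSA sits between the cutoffs
  clogp_hr36 <- -0.31
  bb <- compute_logbb(clogp_hr36, compute_tpsa(HR36_SMILES), cfg)
  expect_equal(as.character(classify_bbb(bb, cfg)), "intermediate")
  # flags are a pure function of the panel
  tr3 <- apply_triage(p2, cns_mpo(p2, cfg), config = cfg)
  expect_identical(tr2$flags, tr3$flags)
})

test_that("MPO is monotone in each property over random panels", {
  panels <- generate_descriptor_table(200, seed = 9)
  worsen <- list(
    clogp = function(p) {p$clogp <- p$clogp + 1.5; p},
    clogd = function(p) {p$clogd <- p$clogd + 1.5; p},
    mw = function(p) {p$mw <- p$mw + 80; p},
    psa = function(p) {p$psa <- p$psa + 40; p},  # above the hump optimum
    hbd = function(p) {p$hbd <- p$hbd + 2; p},
    pka = function(p) {p$pka_basic <- ifelse(is.na(p$pka_basic), 9,
                                             p$pka_basic + 1.5); p}
  )
  for (i in seq_len(nrow(panels))) {
    p <- panels[i, ]
    base <- cns_mpo(p, cfg)$total
    for (w in worsen) {
      expect_lte(cns_mpo(w(p), cfg)$total, base + 1e-12)
    }
  }
})

test_that("triage ranking orders by criteria passed with stated tie-breaks", {
  panels <- cbind(data.frame(id = c("a", "b", "c")),
                  rbind(make_panel(),                    # passes everything
                        make_panel(mpa = 75),            # one fail
                        make_panel(mpa = 75, logs = -5))) # two fails
  out <- triage_library(panels, cfg)
  expect_equal(out$id, c("a", "b", "c"))
  expect_equal(out$rank, 1:3)
})
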
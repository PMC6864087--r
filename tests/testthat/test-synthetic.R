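test_that("the virtual library generator is reproducible from its seed", {
  spec <- synthetic_library_spec(seed = 21)
  a <- generate_virtual_library(spec)
  b <- generate_virtual_library(spec)
  expect_identical(a$compounds, b$compounds)
  expect_identical(a$cv, b$cv)
  c2 <- generate_virtual_library(synthetic_library_spec(seed = 22))
  expect_false(identical(a$cv$mean_cv, c2$cv$mean_cv))
})

test_that("zero noise and no partial effects yield a two-valued CV", {
  lib <- generate_virtual_library(synthetic_library_spec(noise_sd = 0,
                                                         seed = 2))
  expect_setequal(unique(lib$cv$mean_cv), c(5, 92))
  # truth labels are consistent with the generating rule
  expect_identical(lib$truth$true_active, lib$cv$mean_cv == 5)
})

test_that("partial effects lower inactive compounds without touching actives", {
  spec <- synthetic_library_spec(noise_sd = 0, seed = 2,
                                 partial_effects = c(carbonyl_linker = 10))
  lib <- generate_virtual_library(spec)
  inact <- !lib$truth$true_active
  has_carbonyl <- lib$truth$carbonyl_linker
  expect_setequal(unique(lib$cv$mean_cv[inact & has_carbonyl]), 82)
  expect_setequal(unique(lib$cv$mean_cv[inact & !has_carbonyl]), 92)
  expect_setequal(unique(lib$cv$mean_cv[!inact]), 5)
})

test_that("a library larger than the enumeration is rejected", {
  expect_error(generate_virtual_library(
    synthetic_library_spec(n_compounds = 10000)), "exceeds")
  expect_error(synthetic_library_spec(noise_sd = -1))
})

test_that("sampled descriptor panels respect the panel invariants", {
  panels <- generate_descriptor_table(500, seed = 3)
  expect_equal(nrow(panels), 500L)
  expect_true(all(panels$psa >= 0))
  expect_true(all(panels$mpa > 0))
  expect_true(all(panels$hbd >= 0 & panels$hbd == floor(panels$hbd)))
  expect_true(all(panels$mw > 0))
  expect_true(all(is.na(panels$pka_basic) |
                    (panels$pka_basic >= 7 & panels$pka_basic <= 10.5)))
  expect_true(all(panels$clogd <= panels$clogp + 1e-12))
  expect_error(generate_descriptor_table(0), ">= 1")
  expect_identical(generate_descriptor_table(50, seed = 8),
                   generate_descriptor_table(50, seed = 8))
})

test_that("planted-rule recovery degrades monotonically with noise", {
  planted <- synthetic_library_spec()$planted_rule
  recovery <- vapply(c(0, 4, 10, 20), function(sd) {
    hits <- 0L
    for (s in 1:8) {
      lib <- generate_virtual_library(
        synthetic_library_spec(noise_sd = sd, seed = 100 + s))
      fa <- library_flags_activity(lib)
      rule <- tryCatch(induce_rule(fa$flags, fa$activity),
                       error = function(e) NULL)
      if (!is.null(rule) && setequal(rule$required, planted))
        hits <- hits + 1L
    }
    hits
  }, 0L)
  expect_true(all(diff(recovery) <= 0))
  expect_equal(recovery[1], 8L)  # perfect at zero noise
})

test_that("dose-response generation + fitting recovers IC50 within 15%", {
  hits <- 0L
  for (s in 1:10) {
    d <- generate_dose_response(ic50 = 10, hill = 1.5, noise_sd = 4,
                                seed = 200 + s)
    fit <- fit_dose_response(d)
    if (fit$converged && abs(fit$ic50 - 10) / 10 <= 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
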
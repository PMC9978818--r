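test_that("model-order selection is parsimonious on exact models", {
  # pure single exponential -> one component
  one <- simulate_polyclonal_dissociation(0.6, 2e-3, sigma = 0)$phase
  f1 <- paart(one)
  expect_identical(f1$selected_n, 1L)
  # noiseless biphasic, rates 660-fold apart -> two, each within 1%
  two <- simulate_polyclonal_dissociation(c(0.4, 0.1), c(5.6e-5, 3.7e-2),
                                          sigma = 0)$phase
  f2 <- paart(two)
  expect_identical(f2$selected_n, 2L)
  expect_lt(max(abs(f2$components$kd - c(5.6e-5, 3.7e-2)) /
                  c(5.6e-5, 3.7e-2)), 0.01)
  expect_equal(f2$components$fraction, c(0.8, 0.2), tolerance = 1e-6)
  expect_equal(sum(f2$components$fraction), 1, tolerance = 1e-12)
})

test_that("selected model never has worse AIC than the one-component fit", {
  for (s in 1:5) {
    sim <- simulate_polyclonal_dissociation(c(0.3, 0.3), c(2e-4, 2e-2),
                                            sigma = 0.005, seed = 700 + s)
    f <- suppressWarnings(paart(sim$phase))
    expect_lte(f$aic, f$aic_trace$aic[1])
    expect_identical(f$selected_n,
                     f$aic_trace$n[which.min(f$aic_trace$aic)])
  }
})

test_that("closely spaced rates merge into one intermediate component", {
  # 4.3-fold separation is below the resolution limit at this noise level:
  # expect a single component with kd between the truths (a few seeds here;
  # the full stochastic characterization lives in the acceptance suite)
  hit <- 0L
  for (s in 1:5) {
    sim <- simulate_polyclonal_dissociation(c(0.3, 0.3), c(5.6e-5, 2.4e-4),
                                            sigma = 0.005, seed = 40 + s)
    f <- suppressWarnings(paart(sim$phase))
    if (f$selected_n == 1L &&
        f$components$kd > 5.6e-5 && f$components$kd < 2.4e-4)
      hit <- hit + 1L
  }
  expect_gte(hit, 4L)
})

test_that("identical input, control and seed give bit-identical results", {
  sim <- simulate_polyclonal_dissociation(c(0.4, 0.1), c(5.6e-5, 3.7e-2),
                                          sigma = 0.005, seed = 99)
  a <- suppressWarnings(paart(sim$phase))
  b <- suppressWarnings(paart(sim$phase))
  a$phase <- b$phase <- NULL # environments aside, results must be identical
  expect_identical(a[c("selected_n", "components", "rss", "aic",
                       "aic_trace", "fitted_values")],
                   b[c("selected_n", "components", "rss", "aic",
                       "aic_trace", "fitted_values")])
})

test_that("round trip through the competing-analyte dissociation is exact", {
  # the competing model's dissociation is exactly multi-exponential, so
  # avidity binning must recover each kd and the window-start shares
  out <- binary_mixture(seed = 1, sigma = 0)
  f <- paart(out$sensorgram, t_start = 0)
  expect_identical(f$selected_n, 2L)
  truth_kd <- sort(npna3_mabs()$kd[c(1, 3)])
  expect_lt(max(abs(f$components$kd - truth_kd) / truth_kd), 1e-3)
  shares <- truth_shares_at(out$truth, 0)
  # components are ascending in kd, so AB334 (slow) first, AB395 second
  expect_equal(f$components$fraction,
               unname(shares[c("AB334", "AB395")]), tolerance = 1e-3)
})

test_that("standard Langmuir dissociation analysis is the n = 1 baseline", {
  two <- simulate_polyclonal_dissociation(c(0.25, 0.25), c(5.6e-5, 3.7e-2),
                                          sigma = 0)$phase
  lang <- suppressWarnings(fit_langmuir_dissociation(two))
  full <- paart(two)
  expect_identical(lang$selected_n, 1L)
  # on a biphasic input the single-exponential fit is strictly worse
  expect_gt(lang$chi2, full$chi2)
  # weighted-average behavior: the single kd lies between the truths
  expect_gt(lang$components$kd, 5.6e-5)
  expect_lt(lang$components$kd, 3.7e-2)
  # on a pure single exponential both analyses agree
  one <- simulate_polyclonal_dissociation(0.5, 1e-3, sigma = 0)$phase
  expect_equal(fit_langmuir_dissociation(one)$components$kd,
               paart(one)$components$kd, tolerance = 1e-9)
})

test_that("component counting applies the reporting threshold", {
  sim <- simulate_polyclonal_dissociation(c(0.96, 0.04), c(1e-4, 2e-2),
                                          sigma = 0)$phase
  f <- paart(sim)
  expect_identical(f$selected_n, 2L)
  expect_identical(count_components(f, 0.05), 1L)
  expect_identical(count_components(f, 0.03), 2L)
  expect_identical(count_components(f, 0), f$selected_n)
})

test_that("paart methods expose coefficients, predictions and simulations", {
  sim <- simulate_polyclonal_dissociation(c(0.4, 0.1), c(5.6e-5, 3.7e-2),
                                          sigma = 0.003, seed = 2)
  f <- paart(sim$phase)
  cf <- coef(f)
  expect_identical(dim(cf), c(2L, 5L))
  expect_equal(unname(cf[, "fraction"]), f$components$fraction)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, 0), sum(f$components$alpha), tolerance = 1e-12)
  expect_equal(residuals(f), sim$phase$responses - fitted(f))
  s1 <- simulate(f, nsim = 2, seed = 5)
  s2 <- simulate(f, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  expect_identical(dim(s1), c(length(f$residuals), 2L))
  expect_output(print(summary(f)), "Model-order trace")
})
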
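test_that("sum-of-exponentials evaluation matches hand-computed values", {
  expect_equal(sum_exp_response(0, 1, 0.01), 1.0)
  expect_equal(sum_exp_response(log(2) / 0.01, 1, 0.01), 0.5)
  # scalar evaluation: 0.8 e^(-5.6e-5*100) + 0.2 e^(-3.7e-2*100)
  expect_equal(sum_exp_response(100, c(0.8, 0.2), c(5.6e-5, 3.7e-2)),
               0.80048, tolerance = 1e-5)
  # t = 0 equals sum(alpha) + r_inf exactly
  a <- c(0.3, 0.25, 0.1)
  expect_identical(sum_exp_response(0, a, c(1e-4, 1e-3, 1e-2), r_inf = 0.05),
                   sum(a) + 0.05)
  # strictly non-increasing for non-negative parameters
  y <- sum_exp_response(seq(0, 500, 10), a, c(1e-4, 1e-3, 1e-2))
  expect_true(all(diff(y) < 0))
  expect_error(sum_exp_response(1, 1, -0.1), "positive")
  expect_error(sum_exp_response(1, -1, 0.1), "non-negative")
})

test_that("1:1 Langmuir association has the right boundary and limits", {
  ka <- 8.2e4; kd <- 5.6e-5; conc <- 3.33e-8; rmax <- 1.2
  expect_equal(langmuir_association(0, ka, kd, conc, rmax), 0)
  kobs <- ka * conc + kd
  req <- ka * conc * rmax / kobs
  expect_equal(langmuir_association(50 / kobs, ka, kd, conc, rmax), req,
               tolerance = 1e-15)
  # kd -> 0 limit equals rmax (1 - exp(-ka C t))
  t <- seq(0, 300, 10)
  expect_equal(langmuir_association(t, ka, 1e-300, conc, rmax),
               rmax * (1 - exp(-ka * conc * t)), tolerance = 1e-9)
  expect_equal(langmuir_association(t, ka, kd, 0, rmax), rep(0, length(t)))
})

test_that("K_D derivation and kd fold ratios reproduce the reference mAbs", {
  expect_equal(binding_KD(8.2e4, 5.6e-5) * 1e9, 0.68, tolerance = 0.01)
  expect_equal(binding_KD(1, 1), 1)
  expect_equal(binding_KD(4.7e5, 3.7e-2), 7.87234e-8, tolerance = 1e-6)
  expect_error(binding_KD(0, 1), "positive")
  expect_equal(kd_fold_ratio(3.7e-2, 5.6e-5), 660.7, tolerance = 1e-4)
  expect_equal(kd_fold_ratio(2.4e-4, 5.6e-5), 4.3, tolerance = 0.01)
  expect_equal(kd_fold_ratio(0.123, 0.123), 1)
  expect_error(kd_fold_ratio(1, 0), "positive")
})

test_that("single-analyte competing simulation equals the closed form", {
  sys <- competing_system(ka = 8.2e4, kd = 5.6e-5, conc = 3.33e-8,
                          rmax = 0.9)
  sim <- simulate_competing(sys, t_assoc = 300, t_dissoc = 600, dt = 0.5)
  cf <- langmuir_association(sim$assoc$times, 8.2e4, 5.6e-5, 3.33e-8, 0.9)
  expect_lt(max(abs(sim$assoc$total[-1] - cf[-1]) / cf[-1]), 1e-8)
  # occupancy of a single analyte is 1 everywhere past t = 0
  expect_equal(unname(occupancy_fractions(sim, 300)), 1)
})

test_that("two identical analytes at half concentration match one analyte", {
  one <- simulate_competing(
    competing_system(4.7e5, 3.7e-2, 3.33e-8), 300, 300, 1)
  two <- simulate_competing(
    competing_system(c(4.7e5, 4.7e5), c(3.7e-2, 3.7e-2),
                     c(3.33e-8, 3.33e-8) / 2), 300, 300, 1)
  expect_equal(two$assoc$total, one$assoc$total, tolerance = 1e-10)
  expect_equal(unname(occupancy_fractions(two, 300)), c(0.5, 0.5),
               tolerance = 1e-9)
})

test_that("competing simulation matches an independent stiff ODE solver", {
  mabs <- npna3_mabs()[c(1, 3), ]
  conc <- c(0.25, 0.75) * 3.33e-8
  sys <- competing_system(mabs$ka, mabs$kd, conc, labels = mabs$label)
  sim <- simulate_competing(sys, t_assoc = 300, t_dissoc = 60, dt = 1)
  # independent oracle: direct mass-action integration at tight tolerance
  deriv <- function(t, y, p)
    list(p$ka * p$conc * (p$rmax - sum(y)) - p$kd * y)
  ode <- deSolve::lsoda(y = c(0, 0), times = c(0, 300), func = deriv,
                        parms = list(ka = mabs$ka, kd = mabs$kd,
                                     conc = conc, rmax = 1),
                        rtol = 1e-12, atol = 1e-14)
  oracle <- ode[nrow(ode), -1]
  got <- sim$assoc$components[nrow(sim$assoc$components), ]
  expect_lt(max(abs(got - oracle) / oracle), 1e-6)
})

test_that("simulation conserves capacity and dissociates multi-exponentially", {
  mabs <- npna3_mabs()
  sys <- competing_system(mabs$ka, mabs$kd, rep(1.11e-8, 3),
                          labels = mabs$label, rmax = 0.8)
  sim <- simulate_competing(sys, 1800, 600, 1)
  expect_true(all(sim$assoc$total >= -1e-12))
  expect_true(all(sim$assoc$total <= 0.8 + 1e-9))
  # each dissociating component is alpha * exp(-kd t) with alpha = R(t_assoc)
  r_end <- sim$assoc$components[nrow(sim$assoc$components), ]
  for (j in 1:3)
    expect_equal(sim$dissoc$components[, j],
                 r_end[j] * exp(-mabs$kd[j] * sim$dissoc$times),
                 tolerance = 1e-10)
})

test_that("long-run occupancy ratio converges to the closed form", {
  mabs <- npna3_mabs()[c(1, 3), ]
  sys <- competing_system(mabs$ka, mabs$kd, c(0.25, 0.75) * 3.33e-8,
                          labels = mabs$label)
  # slowest k_obs ~ 7.4e-4 1/s; k_obs * t >= 50 needs t >= ~7e4 s
  sim <- simulate_competing(sys, 80000, 10, 20)
  fr <- occupancy_fractions(sim, 80000)
  expect_equal(unname(fr[1] / fr[2]), equilibrium_occupancy_ratio(sys),
               tolerance = 0.01)
  # trivial closed-form cases
  eq <- competing_system(c(1e5, 1e5), c(1e-3, 1e-3), c(1e-8, 1e-8))
  expect_equal(equilibrium_occupancy_ratio(eq), 1.0)
  eq2 <- competing_system(c(1e5, 1e5), c(1e-3, 1e-3), c(2e-8, 1e-8))
  expect_equal(equilibrium_occupancy_ratio(eq2), 2.0)
  expect_error(equilibrium_occupancy_ratio(
    competing_system(1e5, 1e-3, 1e-8)), "two analytes")
})

test_that("slow-analyte occupancy at end of association grows with its length", {
  mabs <- npna3_mabs()[c(1, 3), ]
  sys <- competing_system(mabs$ka, mabs$kd, c(0.25, 0.75) * 3.33e-8,
                          labels = mabs$label)
  fr <- vapply(c(100, 300, 1800), function(ta)
    occupancy_fractions(simulate_competing(sys, ta, 10, 1), ta)[[1]],
    numeric(1L))
  expect_true(all(diff(fr) > 0))
})

test_that("simulations serialize to sensorgrams with component traces", {
  pair <- npna3_mabs()[c(1, 3), ]
  sim <- simulate_competing(
    competing_system(pair$ka, pair$kd, c(0.25, 0.75) * 3.33e-8,
                     labels = pair$label), 300, 600, 1)
  sgs <- competing_sim_sensorgrams(sim, sample_id = "mix")
  expect_length(sgs, 3L)
  expect_identical(vapply(sgs, `[[`, character(1L), "sample_id"),
                   c("mix", "AB334__component", "AB395__component"))
  expect_equal(sgs[[2]]$phases$dissociation$responses +
                 sgs[[3]]$phases$dissociation$responses,
               sgs[[1]]$phases$dissociation$responses, tolerance = 1e-12)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_sensorgrams(sgs, tmp)
  expect_length(read_sensorgrams(tmp), 3L)
})

test_that("occupancy lookup rejects out-of-range times and zero totals", {
  sim <- simulate_competing(competing_system(1e5, 1e-3, 1e-8), 100, 100, 1)
  expect_error(occupancy_fractions(sim, 500), "outside")
  expect_error(occupancy_fractions(sim, 0), "zero")
})
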
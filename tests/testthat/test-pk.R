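test_that("trivial PK limits hold", {
  zero <- two_compartment_pk(0, 1, 10, 50, 5, 60, molecular_weight = 454)
  expect_equal(pk_concentration(zero, c(0, 1, 10)), rep(0, 3))
  # single IV bolus with no peripheral exchange decays mono-exponentially
  bolus <- two_compartment_pk(100, Inf, 10, 50, 0, 60,
                              molecular_weight = 454)
  t <- c(0, 1, 3, 8)
  expect_equal(pk_concentration(bolus, t),
               100 / 50 * exp(-10 / 50 * t) / 454 * 1e6)
})

test_that("empirical profiles interpolate through their samples", {
  prof <- empirical_pk_profile(c(0, 1, 2, 4, 8), c(0, 140, 120, 70, 30),
                               molecular_weight = 409)
  expect_equal(pk_concentration(prof, c(0, 1, 2, 4, 8)),
               c(0, 140, 120, 70, 30) / 409 * 1000)
  # flat extension at the edges
  expect_equal(pk_concentration(prof, 12), 30 / 409 * 1000)
  strict <- empirical_pk_profile(1:5, rep(10, 5), extrapolate = FALSE)
  expect_error(pk_concentration(strict, 0.5), "outside")
  expect_error(empirical_pk_profile(numeric(0), numeric(0)), "at least one")
  expect_error(empirical_pk_profile(c(1, 1, 2), c(1, 2, 3)),
               "strictly increasing")
})

test_that("repeated dosing approaches a periodic steady state", {
  m <- two_compartment_pk(100, 1, 12, 50, 8, 70, interval_h = 24,
                          n_doses = 40, molecular_weight = 454)
  troughs <- pk_concentration(m, c(24, 25, 38, 39) * 24 - 1e-6)
  expect_equal(troughs[2] / troughs[1], 1, tolerance = 1e-3)
  expect_equal(troughs[4] / troughs[3], 1, tolerance = 1e-6)
})

test_that("filtered drug rate is the free-fraction product", {
  expect_equal(filtered_drug_rate(1000, 0.07, 6.5), 455)
  expect_equal(filtered_drug_rate(500, 0.01, 7.0), 35)
  expect_equal(filtered_drug_rate(1000, 0, 6.5), 0)
})

test_that("two-compartment parameters are recovered from clean samples", {
  truth <- two_compartment_pk(100, 1.2, 12, 50, 8, 70, n_doses = 8,
                              molecular_weight = 454)
  samples <- synth_pk_samples(
    truth, c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24) + 7 * 24,
    noise_cv = 0, seed = 1
  )
  init <- two_compartment_pk(100, 0.8, 9, 40, 5, 50, n_doses = 8,
                             molecular_weight = 454)
  fit <- fit_two_compartment(samples, init)
  expect_true(fit$converged)
  est <- tidy(fit)$estimate
  expect_equal(est, c(1.2, 12, 50, 8, 70), tolerance = 0.01)
})

test_that("noisy sparse samples recover clearance and the exposure curve", {
  # with 10% noise on a single 12-sample day profile, the distribution
  # parameters (ka, vc, q, vp) trade off along near-flat likelihood
  # directions; what the data pin down are clearance and the
  # concentration-time course itself
  truth <- two_compartment_pk(100, 1.2, 12, 50, 8, 70, n_doses = 8,
                              molecular_weight = 454)
  tt <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24) + 7 * 24
  curve_err <- vapply(1:5, function(s) {
    samples <- synth_pk_samples(truth, tt, noise_cv = 0.10, seed = 40 + s)
    init <- two_compartment_pk(100, 0.8, 9, 40, 5, 50, n_doses = 8,
                               molecular_weight = 454)
    fit <- suppressWarnings(fit_two_compartment(samples, init))
    expect_lt(abs(fit$model$cl_l_h / 12 - 1), 0.25)
    grid <- seq(7 * 24, 8 * 24, by = 0.5)
    stats::median(abs(pk_concentration(fit$model, grid) /
                        pk_concentration(truth, grid) - 1))
  }, numeric(1))
  expect_lt(stats::median(curve_err), 0.15)
})

test_that("fitting demands at least five samples", {
  truth <- two_compartment_pk(10, 1, 10, 50, 5, 60)
  few <- empirical_pk_profile(1:4, c(10, 8, 6, 4))
  expect_error(fit_two_compartment(few, truth), "at least 5")
})
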
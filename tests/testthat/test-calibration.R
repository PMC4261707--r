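test_that("deviant-glucose exclusion applies the 25% boundary inclusively", {
  # six records, one at 1.30 x the group mean: five retained
  rec <- tibble::tibble(
    glucose_mgdl = c(200, 210, 190, 205, 195, 260),
    target_mgdl = rep(200, 6),
    uge_g = 1:6
  )
  out <- exclude_deviant_points(rec)
  expect_equal(out$n_excluded, 1)
  expect_equal(out$excluded$glucose_mgdl, 260)
  expect_equal(out$fraction_excluded, 1 / 6)
  # exactly at the mean is retained; exactly 1.25 x mean is excluded
  one <- tibble::tibble(glucose_mgdl = c(200, 250), target_mgdl = 200)
  kept <- exclude_deviant_points(one)$records
  expect_equal(kept$glucose_mgdl, 200)
  expect_error(
    exclude_deviant_points(tibble::tibble(glucose_mgdl = 1, target_mgdl = NA)),
    "missing group means"
  )
  expect_error(exclude_deviant_points(tibble::tibble(x = 1)), "must carry")
})

test_that("the objective is zero at the generating truth and rises away from it", {
  d <- synth_shc_uge_dataset(noise_cv = 0, seed = 11)
  truth <- attr(d, "truth")
  expect_lt(uge_objective(truth, d), 1e-20)
  bumped <- truth
  bumped[["vmax2"]] <- truth[["vmax2"]] * 1.2
  expect_gt(uge_objective(bumped, d), 1)
  for (nm in c("vmax1", "km1", "km2", "ki2")) {
    perturbed <- truth
    perturbed[[nm]] <- truth[[nm]] * 1.3
    expect_gt(uge_objective(perturbed, d), uge_objective(truth, d))
  }
})

test_that("steps outside the clinically relevant range carry no weight", {
  d <- synth_shc_uge_dataset(noise_cv = 0, seed = 12)
  truth <- attr(d, "truth")
  corrupted <- d
  out_of_range <- corrupted$glucose_mgdl > 400
  expect_gt(sum(out_of_range), 0)
  corrupted$uge_g[out_of_range] <- corrupted$uge_g[out_of_range] * 100
  expect_equal(uge_objective(truth, corrupted), uge_objective(truth, d))
})

test_that("noise-free two-arm data already identify the baseline kinetics", {
  d <- synth_shc_uge_dataset(noise_cv = 0, seed = 13,
                             arms = c("healthy_baseline", "healthy_drug",
                                      "t2dm_baseline", "t2dm_drug"))
  cal <- calibrate_sglt(d)
  est <- stats::setNames(cal$estimates$estimate, cal$estimates$term)
  expect_true(cal$ki2_identifiable)
  expect_equal(unname(est[names(truth_theta)]), unname(truth_theta),
               tolerance = 0.02)
})

test_that("ki2 is flagged non-identifiable without a drug arm", {
  d <- synth_shc_uge_dataset(noise_cv = 0, seed = 14,
                             arms = c("healthy_baseline", "t2dm_baseline"))
  expect_warning(cal <- calibrate_sglt(d), "non-identifiable")
  expect_false(cal$ki2_identifiable)
  est <- cal$estimates
  expect_false(est$free[est$term == "ki2"])
  expect_equal(est$estimate[est$term == "ki2"], est$start[est$term == "ki2"])
})

test_that("the ODE and steady-state forward models agree on clamp UGE", {
  # long steps so the bladder washout holdup (time constant VX/KX,
  # about 13 min) is small against each window's excreted mass
  d <- synth_shc_uge_dataset(noise_cv = 0, seed = 15,
                             targets_mgdl = c(200, 300, 400),
                             step_duration_h = 3,
                             arms = "t2dm_baseline")
  truth <- attr(d, "truth")
  ss <- predict_stepwise_uge(d, truth, method = "steady_state")
  od <- predict_stepwise_uge(d, truth, method = "ode")
  # urine collection lags the quasi-steady account, never leads it
  expect_true(all(od <= ss + 1e-6))
  expect_equal(od, ss, tolerance = 0.15)
  expect_equal(sum(od), sum(ss), tolerance = 0.1)
})
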
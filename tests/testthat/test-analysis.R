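test_that("shares degenerate correctly when one transporter is absent", {
  geom <- build_geometry(sglt_physiology(),
                         sglt_transporters("healthy", vmax1_mmol_h = 0))
  sim <- simulate_tubule(geom, forcing_constant(200, 6.5), seq(0, 2, 0.1))
  contrib <- transporter_contributions(sim)
  expect_equal(contrib$share_sglt2, 1)
  expect_equal(contrib$share_sglt1, 0)
})

test_that("zero reabsorption flags undefined shares", {
  geom <- build_geometry(
    sglt_physiology(),
    sglt_transporters("healthy", vmax1_mmol_h = 0, vmax2_mmol_h = 0)
  )
  sim <- simulate_tubule(geom, forcing_constant(200, 6.5), seq(0, 1, 0.1))
  expect_warning(contrib <- transporter_contributions(sim), "undefined")
  expect_true(is.na(contrib$share_sglt2))
})

test_that("operation efficiency is bounded and saturates with glucose", {
  geom <- healthy_geometry()
  eff <- vapply(c(100, 400, 3000), function(g) {
    sim <- simulate_tubule(geom, forcing_constant(g, 6.5), seq(0, 1, 0.1))
    unlist(operation_efficiency(sim)[c("efficiency_sglt1",
                                       "efficiency_sglt2")])
  }, numeric(2))
  expect_true(all(eff >= 0 & eff <= 1))
  expect_true(all(diff(t(eff)) > 0)) # increases with glucose for both
  expect_true(all(eff[, 3] > 0.95))  # near saturation far above Km
})

test_that("steady-state and windowed simulation summaries agree", {
  geom <- healthy_geometry()
  ss <- steady_state_profile(geom, 250)
  sim <- simulate_tubule(geom, forcing_constant(250, 6.5), seq(0, 2, 0.1))
  contrib <- transporter_contributions(sim)
  eff <- operation_efficiency(sim)
  expect_equal(contrib$share_sglt2, ss$share_sglt2, tolerance = 1e-6)
  expect_equal(eff$efficiency_sglt2, ss$efficiency_sglt2, tolerance = 1e-6)
  expect_equal(eff$efficiency_sglt1, ss$efficiency_sglt1, tolerance = 1e-6)
})

test_that("occupancy limits behave at zero and saturating exposure", {
  geom <- t2dm_geometry(inhibitor = sglt_inhibitor("dapagliflozin"))
  none <- occupancy_and_residual(steady_state_profile(geom, 150, drug_nm = 0))
  expect_equal(none$occupancy_sglt2, 0)
  base_sglt2 <- steady_state_profile(geom, 150)$sglt2_mmol_h
  expect_equal(none$residual_sglt2_mmol_h, base_sglt2)
  sat <- occupancy_and_residual(
    steady_state_profile(geom, 150, drug_nm = 1e9)
  )
  expect_gt(sat$occupancy_sglt2, 0.999999)
  expect_lt(sat$residual_sglt2_mmol_h, 1e-3)
  # plasma-based convention is available and bounded
  pl <- occupancy_and_residual(steady_state_profile(geom, 150, drug_nm = 245),
                               basis = "plasma")
  expect_true(pl$occupancy_sglt2 > 0 && pl$occupancy_sglt2 < 1)
})

test_that("SGLT1's share of reabsorption grows with drug exposure", {
  geom <- t2dm_geometry(inhibitor = sglt_inhibitor("dapagliflozin"))
  shares <- vapply(c(0, 10, 100, 1000), function(d) {
    steady_state_profile(geom, 150, drug_nm = d)$share_sglt1
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
  expect_gt(shares[4], 0.5) # SGLT1 becomes the predominant pathway
})

test_that("loss-of-function scans are monotone and rank the transporters", {
  prof <- synth_daily_glucose_profile(seed = 7)
  s2 <- loss_of_function_scan("sglt2", c(0, 0.5, 1), prof,
                              gfr_l_per_h = 7.4)
  s1 <- loss_of_function_scan("sglt1", c(0, 1), prof, gfr_l_per_h = 7.4)
  expect_equal(s2$reduction_pct[1], 0)
  expect_lt(s2$uge_g[1], 0.5)
  expect_true(all(diff(s2$uge_g) > 0))
  expect_true(all(diff(s2$reduction_pct) > 0))
  # complete SGLT1 loss is far milder than complete SGLT2 loss
  expect_lt(s1$reduction_pct[2], s2$reduction_pct[3])
  expect_lt(s1$uge_g[2], s2$uge_g[3])
})

test_that("diabetic SGLT2 loss reduces reabsorption at least as much as healthy", {
  reduction <- function(trans, gfr) {
    geom1 <- build_geometry(sglt_physiology(), trans)
    trans0 <- trans
    trans0$vmax2_mmol_h <- 0
    geom0 <- build_geometry(sglt_physiology(), trans0)
    reab <- function(g) {
      ss <- steady_state_profile(g, 150, gfr_l_per_h = gfr)
      ss$sglt1_mmol_h + ss$sglt2_mmol_h
    }
    100 * (1 - reab(geom0) / reab(geom1))
  }
  expect_gte(reduction(sglt_transporters("t2dm"), 7.0),
             reduction(sglt_transporters("healthy"), 7.0))
})

test_that("clamp UGE is only weakly sensitive to the inhibitor's SGLT1 affinity", {
  proto <- make_shc_protocol(seq(100, 350, by = 50), gfr_by_step = 7,
                             drug = 245)
  # a 1,667-fold change in Ki1 (20x selective dual inhibitor vs highly
  # selective) moves clamp UGE by only a few percent: luminal glucose in
  # the PST is so far above Km1 that competitive inhibition is swamped
  scan <- sensitivity_scan("ki1", c(6, 10000), proto,
                           transporters = sglt_transporters("t2dm"),
                           inhibitor = sglt_inhibitor("dapagliflozin"))
  expect_lt(abs(scan$uge_g[1] / scan$uge_g[2] - 1), 0.10)
})

test_that("reducing SGLT1 capacity under SGLT2 inhibition augments glucosuria", {
  proto <- make_shc_protocol(seq(100, 350, by = 50), gfr_by_step = 7,
                             drug = 245)
  scan <- sensitivity_scan("vmax1", c(14, 20), proto,
                           transporters = sglt_transporters("t2dm"),
                           inhibitor = sglt_inhibitor("dapagliflozin"))
  expect_gt(scan$uge_g[1], scan$uge_g[2]) # 30 % less SGLT1 -> more UGE
  expect_equal(scan$pct_change[2], 0, tolerance = 1e-8)
  # determinism: identical values give identical UGE
  expect_equal(scan$uge_g[2], attr(scan, "baseline_uge_g"))
})
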
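test_that("the default clamp staircase spans 4 h in six 40-min steps", {
  proto <- make_shc_protocol(seq(100, 350, by = 50))
  expect_equal(nrow(proto), 6)
  expect_equal(max(proto$t_end_h), 4)
  expect_equal(unique(round(proto$t_end_h - proto$t_start_h, 10)), 2 / 3)
  f <- as_forcing(proto)
  expect_equal(f$cglu_mm(0.1), convert_units(100, "mg/dL", "mM"))
  expect_equal(f$cglu_mm(3.9), convert_units(350, "mg/dL", "mM"))
  expect_equal(f$breaks, proto$t_start_h[-1])
})

test_that("a single-step protocol degenerates to constant forcing", {
  proto <- make_shc_protocol(180, step_duration_h = 2, gfr_by_step = 7)
  f <- as_forcing(proto)
  fc <- forcing_constant(180, 7)
  t <- seq(0, 2, 0.25)
  expect_equal(f$cglu_mm(t), fc$cglu_mm(t))
  expect_equal(f$gfr_l_per_h(t), fc$gfr_l_per_h(t))
})

test_that("mismatched per-step arrays are rejected", {
  expect_error(make_shc_protocol(c(100, 150), gfr_by_step = c(6, 7, 8)),
               "length 1 or 2")
})

test_that("the synthetic daily profile honours its constraints", {
  prof <- synth_daily_glucose_profile(90, 80, 125, seed = 1)
  expect_equal(attr(prof, "mean_mgdl"), 90, tolerance = 0.5 / 90)
  expect_true(all(prof$glucose_mgdl >= 80 & prof$glucose_mgdl <= 125))
  # three post-meal excursions: at least 3 local maxima above 105
  peaks <- with(rle(prof$glucose_mgdl > 105), sum(values))
  expect_gte(peaks, 3)
  # deterministic in the seed
  expect_identical(prof, synth_daily_glucose_profile(90, 80, 125, seed = 1))
  expect_false(identical(
    prof$glucose_mgdl,
    synth_daily_glucose_profile(90, 80, 125, seed = 2)$glucose_mgdl
  ))
})

test_that("degenerate and infeasible profile requests behave", {
  flat <- synth_daily_glucose_profile(100, 100, 100)
  expect_equal(unique(flat$glucose_mgdl), 100)
  expect_error(synth_daily_glucose_profile(70, 80, 125), "min_mgdl <=")
})

test_that("per-step UGE accounting is additive and conservative", {
  geom <- build_geometry(
    sglt_physiology(),
    sglt_transporters("healthy", vmax1_mmol_h = 0, vmax2_mmol_h = 0)
  )
  # long steps so the bladder holdup (urine is ~180x more concentrated
  # than filtrate at KX = 0.6 L/h) is small against each window's mass
  proto <- make_shc_protocol(seq(100, 300, by = 50), step_duration_h = 4)
  tt <- sort(unique(c(seq(0, max(proto$t_end_h), 0.05), proto$t_end_h)))
  sim <- simulate_tubule(geom, as_forcing(proto), tt)
  uge <- stepwise_uge(sim, proto)
  expect_true(all(uge$uge_g >= 0))
  expect_equal(cumsum(uge$uge_g), uge$uge_cum_g)
  # zero reabsorption: excreted mass equals filtered mass per step, up to
  # the transit holdup that shifts mass between windows
  expect_equal(uge$uge_g, uge$filtered_g, tolerance = 0.1)
  expect_equal(sum(uge$uge_g), sum(uge$filtered_g), tolerance = 0.05)
  # exact accounting: filtered = excreted + change in tubule + bladder load
  ts <- sim$timeseries
  content <- rowSums(ts[paste0("glu_", geom$segment)]) + ts$glu_bladder
  expect_equal(sum(uge$uge_g) + convert_units(content[nrow(ts)] - content[1],
                                              "mmol", "g"),
               sum(uge$filtered_g), tolerance = 1e-6)
  expect_true(all(diff(uge$uge_g) > 0)) # monotone in the glucose target
})

test_that("healthy baseline excretes essentially nothing at 100 mg/dL", {
  geom <- healthy_geometry()
  proto <- make_shc_protocol(100, step_duration_h = 1)
  sim <- simulate_tubule(geom, as_forcing(proto), seq(0, 1, 0.05))
  expect_lt(stepwise_uge(sim, proto)$uge_g, 0.01)
})

test_that("windows outside the simulated span are rejected", {
  geom <- healthy_geometry()
  proto <- make_shc_protocol(c(100, 150))
  sim <- simulate_tubule(geom, as_forcing(proto), seq(0, 1, 0.1))
  expect_error(stepwise_uge(sim, proto), "does not cover")
})
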
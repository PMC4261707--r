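test_that("each segment's root satisfies its mass balance exactly", {
  geom <- healthy_geometry(inhibitor = sglt_inhibitor("dapagliflozin"))
  for (glucose in c(80, 150, 300, 550)) {
    for (drug in c(0, 50, 500)) {
      ss <- steady_state_profile(geom, glucose, drug_nm = drug)
      seg <- ss$segments
      # inflow = convective outflow + reabsorption, segment by segment
      expect_equal(seg$inflow_mmol_h,
                   seg$outflow_mmol_h + seg$rate_mmol_h,
                   tolerance = 1e-12)
      # chaining: outflow of j is inflow of j+1, last outflow is the UGE rate
      expect_equal(seg$inflow_mmol_h[-1], seg$outflow_mmol_h[-9])
      expect_equal(ss$uge_mmol_h, seg$outflow_mmol_h[9])
    }
  }
})

test_that("without transporters the filtrate is only concentrated by water removal", {
  geom <- build_geometry(
    sglt_physiology(),
    sglt_transporters("healthy", vmax1_mmol_h = 0, vmax2_mmol_h = 0)
  )
  ss <- steady_state_profile(geom, 200)
  filtered <- 6.5 * convert_units(200, "mg/dL", "mM")
  expect_equal(ss$segments$c_glu_mm,
               filtered / ss$segments$outflow_l_per_h)
  expect_equal(ss$uge_mmol_h, filtered)
  expect_equal(ss$sglt1_mmol_h + ss$sglt2_mmol_h, 0)
})

test_that("luminal drug concentration rises monotonically along the tubule", {
  geom <- t2dm_geometry(inhibitor = sglt_inhibitor("dapagliflozin"))
  ss <- steady_state_profile(geom, 150, drug_nm = 245)
  expect_true(all(diff(ss$segments$c_drug_nm) > 0))
  # filtration-only steady state: c_drug = fup * GFR * Cp / Q
  expect_equal(ss$segments$c_drug_nm,
               0.07 * 7 * 245 / ss$segments$outflow_l_per_h)
})

test_that("SGLT2-selective inhibition at saturating exposure spares a high-Ki1 PST", {
  inh <- sglt_inhibitor("x", molecular_weight = 409, free_fraction = 0.07,
                        ki1_nm = 1e15, ki2_nm = 0.3)
  geom <- healthy_geometry(inhibitor = inh)
  ss_drug <- steady_state_profile(geom, 250, drug_nm = 1e7)
  expect_lt(ss_drug$sglt2_mmol_h, 0.05)
  # PST sees the full load; solve the PST-only system as reference
  geom_nopct <- build_geometry(sglt_physiology(),
                               sglt_transporters("healthy", vmax2_mmol_h = 0))
  ss_ref <- steady_state_profile(geom_nopct, 250)
  expect_equal(ss_drug$sglt1_mmol_h, ss_ref$sglt1_mmol_h, tolerance = 1e-3)
})

test_that("UGE shows a renal threshold and approaches the capacity asymptote", {
  geom <- healthy_geometry()
  low <- steady_state_profile(geom, 100)
  expect_lt(mmol_to_g(low$uge_mmol_h) * 24, 0.5) # near-complete reabsorption
  high <- steady_state_profile(geom, 2000)
  asymptote <- high$filtered_mmol_h - 113.5
  expect_gt(high$uge_mmol_h, asymptote)
  expect_lt((high$uge_mmol_h - asymptote) / high$filtered_mmol_h, 0.02)
  # monotone splay in between
  uge <- vapply(seq(50, 600, by = 50),
                function(g) steady_state_profile(geom, g)$uge_mmol_h,
                numeric(1))
  expect_true(all(diff(uge) >= 0))
})

test_that("reabsorption responds monotonically to kinetic parameters", {
  total_reab <- function(...) {
    geom <- build_geometry(sglt_physiology(), sglt_transporters("healthy", ...))
    ss <- steady_state_profile(geom, 250)
    ss$sglt1_mmol_h + ss$sglt2_mmol_h
  }
  expect_true(all(diff(vapply(c(50, 93.5, 150),
    function(v) total_reab(vmax2_mmol_h = v), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(5, 20, 40),
    function(v) total_reab(vmax1_mmol_h = v), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(2, 4, 8),
    function(k) total_reab(km2_mm = k), numeric(1))) < 0))
  expect_true(all(diff(vapply(c(0.25, 0.5, 1),
    function(k) total_reab(km1_mm = k), numeric(1))) < 0))
  geomd <- healthy_geometry(inhibitor = sglt_inhibitor("dapagliflozin"))
  reab_drug <- vapply(c(0, 10, 100, 1000), function(d) {
    ss <- steady_state_profile(geomd, 250, drug_nm = d)
    ss$sglt1_mmol_h + ss$sglt2_mmol_h
  }, numeric(1))
  expect_true(all(diff(reab_drug) < 0))
})

test_that("drug forcing without an inhibitor in the geometry is rejected", {
  expect_error(steady_state_profile(healthy_geometry(), 100, drug_nm = 10),
               "no inhibitor")
})
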
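# shared fixtures; everything is built in code, no stored data
healthy_geometry <- function(gfr = 6.5, inhibitor = NULL, ...) {
  build_geometry(sglt_physiology(gfr_l_per_h = gfr),
                 sglt_transporters("healthy", ...), inhibitor)
}

t2dm_geometry <- function(gfr = 7.0, inhibitor = NULL, ...) {
  build_geometry(sglt_physiology(gfr_l_per_h = gfr),
                 sglt_transporters("t2dm", ...), inhibitor)
}

# truth used across recovery tests (registry values)
truth_theta <- c(vmax1 = 20, vmax2 = 110, prop_healthy = 93.5 / 110,
                 km1 = 0.5, km2 = 4.0, ki2 = 0.3)

# long-run ODE solution under constant forcing, for oracle comparisons
settle <- function(geometry, forcing, hours = 6) {
  simulate_tubule(geometry, forcing, seq(0, hours, length.out = 25),
                  init = "empty")
}

last_segment_conc <- function(sim) {
  geom <- sim$geometry
  ts <- sim$timeseries[nrow(sim$timeseries), ]
  vapply(seq_len(nrow(geom)), function(j) {
    ts[[paste0("glu_", geom$segment[j])]] / geom$volume_l[j]
  }, numeric(1))
}
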
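normalize_windows <- function(windows, sim) {
  ts <- sim$timeseries
  if (is.null(windows)) {
    return(tibble::tibble(window = 1L, t_start_h = min(ts$time),
                          t_end_h = max(ts$time)))
  }
  if (inherits(windows, "sglt_protocol")) {
    return(tibble::tibble(window = windows$step,
                          target_mgdl = windows$target_mgdl,
                          t_start_h = windows$t_start_h,
                          t_end_h = windows$t_end_h))
  }
  stopifnot(all(c("t_start_h", "t_end_h") %in% names(windows)))
  out <- tibble::as_tibble(windows)
  if (!"window" %in% names(out)) out$window <- seq_len(nrow(out))
  out
}

window_delta <- function(sim, col, windows) {
  ts <- sim$timeseries
  if (min(windows$t_start_h) < min(ts$time) - 1e-9 ||
      max(windows$t_end_h) > max(ts$time) + 1e-9) {
    stop("accounting window outside the simulated span", call. = FALSE)
  }
  at <- function(t) stats::approx(ts$time, ts[[col]], xout = t)$y
  at(windows$t_end_h) - at(windows$t_start_h)
}

#' Reabsorbed mass and transporter shares per accounting window
#'
#' Integrates the SGLT2 (PCT) and SGLT1 (PST) reabsorption accumulators
#' over each window and reports the absolute amounts and the relative
#' contributions of the two transporters.
#'
#' @param sim an [simulate_tubule()] result.
#' @param windows `NULL` (whole run), an `sglt_protocol` (per-step), or a
#'   tibble with `t_start_h`/`t_end_h` columns.
#' @return tibble: window id, `sglt1_mmol`, `sglt2_mmol`, `total_mmol`,
#'   `share_sglt1`, `share_sglt2` (shares are `NA` when nothing was
#'   reabsorbed in the window).
#' @export
transporter_contributions <- function(sim, windows = NULL) {
  w <- normalize_windows(windows, sim)
  s1 <- window_delta(sim, "reab_sglt1", w)
  s2 <- window_delta(sim, "reab_sglt2", w)
  total <- s1 + s2
  if (any(total <= 0)) {
    warning("window(s) with zero total reabsorption: shares undefined",
            call. = FALSE)
  }
  dplyr::mutate(w,
    sglt1_mmol = s1, sglt2_mmol = s2, total_mmol = total,
    share_sglt1 = ifelse(total > 0, s1 / total, NA_real_),
    share_sglt2 = ifelse(total > 0, s2 / total, NA_real_)
  )
}

#' Transporter operation efficiency per accounting window
#'
#' Operation efficiency is the window-averaged reabsorption rate of a
#' transporter expressed as a fraction of its whole-kidney capacity
#' (`rate / Vmax`), i.e. how hard the pool of transporters is working.
#'
#' @inheritParams transporter_contributions
#' @return tibble: window id, `efficiency_sglt1`, `efficiency_sglt2`.
#' @export
operation_efficiency <- function(sim, windows = NULL) {
  w <- normalize_windows(windows, sim)
  geom <- sim$geometry
  vmax1 <- sum(geom$vmax_mmol_h[geom$kind == "PST"])
  vmax2 <- sum(geom$vmax_mmol_h[geom$kind == "PCT"])
  dur <- w$t_end_h - w$t_start_h
  r1 <- window_delta(sim, "reab_sglt1", w) / dur
  r2 <- window_delta(sim, "reab_sglt2", w) / dur
  dplyr::mutate(w,
    efficiency_sglt1 = if (vmax1 > 0) r1 / vmax1 else NA_real_,
    efficiency_sglt2 = if (vmax2 > 0) r2 / vmax2 else NA_real_
  )
}

run_daily <- function(transporters, profile, gfr_l_per_h, kx_l_per_h,
                      physiology, dt_h = 0.05) {
  phys <- physiology
  phys$gfr_l_per_h <- gfr_l_per_h
  phys$urine_outflow_l_per_h <- kx_l_per_h
  geom <- build_geometry(phys, transporters)
  forcing <- as_forcing(profile, gfr_l_per_h = gfr_l_per_h,
                        kx_l_per_h = kx_l_per_h)
  simulate_tubule(geom, forcing, seq(0, 24, by = dt_h),
                  init = "empty", burn_in_h = 2)
}

#' Loss-of-function scan: UGE and reabsorption vs. residual capacity
#'
#' Emulates loss-of-function mutations of a transporter by scaling its
#' capacity: for each fraction `f` the transporter's `Vmax` is multiplied
#' by `(1 - f)` and a full 24-h simulation is run under a daily plasma
#' glucose profile. Reports daily urinary glucose (g) and the percent
#' reduction in total reabsorption relative to the intact (`f = 0`) run.
#'
#' @param transporter `"sglt2"` or `"sglt1"`.
#' @param fractions lost-capacity fractions in `[0, 1]`.
#' @param profile an [synth_daily_glucose_profile()] (or compatible) daily
#'   profile.
#' @param transporters baseline [sglt_transporters()].
#' @param gfr_l_per_h,kx_l_per_h constant GFR and urine outflow, L/h.
#' @param physiology an [sglt_physiology()] object.
#' @return tibble: `fraction`, `uge_g`, `reabsorbed_mmol`,
#'   `reduction_pct` (percent reduction of daily reabsorption vs intact).
#' @export
loss_of_function_scan <- function(transporter = c("sglt2", "sglt1"),
                                  fractions,
                                  profile,
                                  transporters = sglt_transporters("healthy"),
                                  gfr_l_per_h = 7.4, kx_l_per_h = 0.6,
                                  physiology = sglt_physiology()) {
  transporter <- match.arg(transporter)
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  intact <- run_daily(transporters, profile, gfr_l_per_h, kx_l_per_h,
                      physiology)
  base <- glance(intact)
  one <- function(f) {
    tr <- transporters
    if (transporter == "sglt2") {
      tr$vmax2_mmol_h <- tr$vmax2_mmol_h * (1 - f)
    } else {
      tr$vmax1_mmol_h <- tr$vmax1_mmol_h * (1 - f)
    }
    g <- glance(run_daily(tr, profile, gfr_l_per_h, kx_l_per_h, physiology))
    tibble::tibble(
      fraction = f,
      uge_g = g$uge_g,
      reabsorbed_mmol = g$reabsorbed_mmol,
      reduction_pct = 100 * (1 - g$reabsorbed_mmol / base$reabsorbed_mmol)
    )
  }
  out <- purrr::map_dfr(fractions, one)
  attr(out, "intact") <- base
  attr(out, "transporter") <- transporter
  class(out) <- c("sglt_lof_scan", class(out))
  out
}

#' Sensitivity of clamp UGE to SGLT1 kinetics
#'
#' Re-simulates a stepped hyperglycemic clamp while varying one SGLT1
#' parameter (`vmax1`, `km1`, or -- with an inhibitor present -- `ki1`)
#' and reports total protocol UGE per tested value, plus the percent
#' change relative to the unmodified parameter set.
#'
#' @param param `"vmax1"`, `"km1"`, or `"ki1"`.
#' @param values positive parameter values to test (mmol/h, mM, or nM).
#' @param protocol an [make_shc_protocol()] protocol (its attached drug
#'   input, if any, is used for every run).
#' @param transporters baseline [sglt_transporters()].
#' @param inhibitor [sglt_inhibitor()]; required when `param = "ki1"` or
#'   when the protocol carries a drug input.
#' @param physiology an [sglt_physiology()] object.
#' @return tibble: `param`, `value`, `uge_g`, `pct_change` (vs the
#'   baseline parameter value).
#' @export
sensitivity_scan <- function(param = c("vmax1", "km1", "ki1"), values,
                             protocol,
                             transporters = sglt_transporters("t2dm"),
                             inhibitor = NULL,
                             physiology = sglt_physiology()) {
  param <- match.arg(param)
  stopifnot(all(values > 0))
  if (param == "ki1" && is.null(inhibitor)) {
    stop("`ki1` sensitivity requires an inhibitor", call. = FALSE)
  }
  run <- function(tr, inh) {
    geom <- build_geometry(physiology, tr, inh)
    forcing <- as_forcing(protocol)
    tt <- sort(unique(c(seq(min(protocol$t_start_h), max(protocol$t_end_h),
                            by = 0.02), protocol$t_end_h)))
    sim <- simulate_tubule(geom, forcing, tt)
    sum(stepwise_uge(sim, protocol)$uge_g)
  }
  base_uge <- run(transporters, inhibitor)
  out <- purrr::map_dfr(values, function(v) {
    tr <- transporters
    inh <- inhibitor
    if (param == "vmax1") tr$vmax1_mmol_h <- v
    if (param == "km1") tr$km1_mm <- v
    if (param == "ki1") inh$ki1_nm <- v
    tibble::tibble(param = param, value = v, uge_g = run(tr, inh))
  })
  out$pct_change <- 100 * (out$uge_g / base_uge - 1)
  attr(out, "baseline_uge_g") <- base_uge
  out
}

#' SGLT2 occupancy and residual SGLT2 activity
#'
#' Occupancy of SGLT2 by the inhibitor is computed from the luminal drug
#' concentration at the site of competition (the PCT sub-segments) as
#' `C_drug / (C_drug + Ki2)`, averaged across PCT sub-segments (and over
#' time for simulations); `basis = "plasma"` instead uses the unbound
#' plasma concentration. Residual SGLT2 activity is the SGLT2-mediated
#' reabsorption rate that persists under inhibition.
#'
#' @param x an `sglt_steady_state` or `sglt_simulation`.
#' @param windows accounting windows (simulation method only; see
#'   [transporter_contributions()]).
#' @param basis `"luminal"` (default) or `"plasma"`.
#' @return tibble with `occupancy_sglt2` (fraction) and
#'   `residual_sglt2_mmol_h`.
#' @export
occupancy_and_residual <- function(x, windows = NULL,
                                   basis = c("luminal", "plasma")) {
  basis <- match.arg(basis)
  UseMethod("occupancy_and_residual")
}

#' @export
occupancy_and_residual.sglt_steady_state <- function(x, windows = NULL,
                                                     basis = c("luminal", "plasma")) {
  basis <- match.arg(basis)
  pct <- x$segments[x$segments$kind == "PCT", ]
  ki2 <- pct$ki_nm[1]
  cd <- if (basis == "luminal") pct$c_drug_nm else
    rep(x$free_fraction * x$drug_nm, nrow(pct))
  occ <- if (is.finite(ki2)) mean(cd / (cd + ki2)) else 0
  tibble::tibble(occupancy_sglt2 = occ, residual_sglt2_mmol_h = x$sglt2_mmol_h)
}

#' @export
occupancy_and_residual.sglt_simulation <- function(x, windows = NULL,
                                                   basis = c("luminal", "plasma")) {
  basis <- match.arg(basis)
  w <- normalize_windows(windows, x)
  geom <- x$geometry
  pct <- geom[geom$kind == "PCT", ]
  ki2 <- pct$ki_nm[1]
  ts <- x$timeseries
  fup <- attr(geom, "free_fraction")
  occ_t <- if (!is.finite(ki2)) rep(0, nrow(ts)) else if (basis == "luminal") {
    rowMeans(sapply(seq_len(nrow(pct)), function(j) {
      cd <- ts[[paste0("drug_", pct$segment[j])]] / pct$volume_l[j]
      cd / (cd + ki2)
    }))
  } else {
    cd <- fup * ts$plasma_drug_nm
    cd / (cd + ki2)
  }
  res <- purrr::map_dfr(seq_len(nrow(w)), function(i) {
    inw <- ts$time >= w$t_start_h[i] & ts$time <= w$t_end_h[i]
    dur <- w$t_end_h[i] - w$t_start_h[i]
    tibble::tibble(
      occupancy_sglt2 = mean(occ_t[inw]),
      residual_sglt2_mmol_h =
        window_delta(x, "reab_sglt2", w[i, , drop = FALSE]) / dur
    )
  })
  dplyr::bind_cols(w, res)
}
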
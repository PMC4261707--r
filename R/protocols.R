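#' Stepped hyperglycemic clamp (SHC) protocol
#'
#' Builds the piecewise-constant plasma-glucose staircase used in clamp
#' studies: plasma glucose is held at each target for a fixed step
#' duration while GFR and urine outflow are constant per step. The
#' default step duration of 40 min makes the canonical 100-350 mg/dL
#' escalation (six 50 mg/dL increments) span 4 h.
#'
#' @param targets_mgdl per-step plasma glucose targets, mg/dL.
#' @param step_duration_h duration of each step, h (default 2/3 h).
#' @param gfr_by_step GFR, L/h: scalar or one value per step.
#' @param kx_by_step urine outflow, L/h: scalar or one value per step.
#' @param drug optional drug input: a [two_compartment_pk()], an
#'   [empirical_pk_profile()], or a constant total plasma concentration
#'   in nM.
#' @param inhibitor the [sglt_inhibitor()] the drug input refers to
#'   (required when `drug` is given as a bare number).
#' @param t_start_h protocol start time, h.
#' @return an object of class `sglt_protocol`: a tibble with one row per
#'   step (`step`, `target_mgdl`, `t_start_h`, `t_end_h`, `gfr_l_per_h`,
#'   `kx_l_per_h`) and the drug input attached as attribute `drug`.
#' @examples
#' make_shc_protocol(seq(100, 350, by = 50))
#' @export
make_shc_protocol <- function(targets_mgdl, step_duration_h = 2 / 3,
                              gfr_by_step = 6.5, kx_by_step = 0.6,
                              drug = NULL, inhibitor = NULL, t_start_h = 0) {
  n <- length(targets_mgdl)
  stopifnot(n >= 1, all(targets_mgdl > 0), all(step_duration_h > 0))
  dur <- rep_len(step_duration_h, n)
  if (!(length(gfr_by_step) %in% c(1, n)) ||
      !(length(kx_by_step) %in% c(1, n))) {
    stop("per-step GFR/urine-outflow arrays must have length 1 or ",
         n, call. = FALSE)
  }
  ends <- t_start_h + cumsum(dur)
  proto <- tibble::tibble(
    step = seq_len(n),
    target_mgdl = as.numeric(targets_mgdl),
    t_start_h = c(t_start_h, ends[-n]),
    t_end_h = ends,
    gfr_l_per_h = rep_len(gfr_by_step, n),
    kx_l_per_h = rep_len(kx_by_step, n)
  )
  attr(proto, "drug") <- drug
  attr(proto, "inhibitor") <- inhibitor
  class(proto) <- c("sglt_protocol", class(proto))
  proto
}

step_fun <- function(t_edges, values) {
  force(t_edges); force(values)
  function(t) {
    idx <- pmin(pmax(findInterval(t, t_edges, left.open = FALSE), 1),
                length(values))
    values[idx]
  }
}

drug_conc_fun <- function(drug) {
  if (is.null(drug)) return(function(t) rep_len(0, length(t)))
  if (is.numeric(drug) && length(drug) == 1) {
    return(function(t) rep_len(drug, length(t)))
  }
  if (inherits(drug, "two_compartment_pk") ||
      inherits(drug, "empirical_pk_profile")) {
    return(function(t) pk_concentration(drug, t))
  }
  stop("unsupported drug input", call. = FALSE)
}

#' Forcing functions from a protocol or daily profile
#'
#' @param x an `sglt_protocol` or `sglt_daily_profile`.
#' @param ... passed to methods.
#' @return an [sglt_forcing()] object.
#' @export
as_forcing <- function(x, ...) UseMethod("as_forcing")

#' @rdname as_forcing
#' @export
as_forcing.sglt_protocol <- function(x, ...) {
  edges <- x$t_start_h
  sglt_forcing(
    cglu_mm = step_fun(edges, mgdl_to_mm(x$target_mgdl)),
    gfr_l_per_h = step_fun(edges, x$gfr_l_per_h),
    kx_l_per_h = step_fun(edges, x$kx_l_per_h),
    cdrug_nm = drug_conc_fun(attr(x, "drug")),
    breaks = c(x$t_start_h[-1])
  )
}

#' @rdname as_forcing
#' @param gfr_l_per_h,kx_l_per_h constant GFR and urine outflow for the
#'   daily-profile method.
#' @param drug optional drug input (see [make_shc_protocol()]).
#' @export
as_forcing.sglt_daily_profile <- function(x, gfr_l_per_h = 6.5,
                                          kx_l_per_h = 0.6, drug = NULL, ...) {
  f <- stats::approxfun(x$time_h, mgdl_to_mm(x$glucose_mgdl), rule = 2)
  sglt_forcing(
    cglu_mm = f,
    gfr_l_per_h = gfr_l_per_h,
    kx_l_per_h = kx_l_per_h,
    cdrug_nm = drug_conc_fun(drug)
  )
}

#' Synthetic 24-h normoglycemic plasma glucose profile
#'
#' Emulates a healthy daily glucose trace: a nocturnal plateau near the
#' lower bound, a slightly higher daytime baseline, and three post-meal
#' excursions (0.5 h linear rise, 1 h exponential decay). Excursion
#' amplitudes are rescaled analytically so the time-weighted 24-h mean
#' equals `mean_mgdl` exactly; the resulting trace is checked to stay
#' within `[min_mgdl, max_mgdl]`. With a seed, meal times (+/- 15 min)
#' and relative meal amplitudes (+/- 5 %) are jittered deterministically.
#'
#' @param mean_mgdl target time-weighted mean, mg/dL.
#' @param min_mgdl,max_mgdl admissible range, mg/dL.
#' @param meal_times meal start times, h.
#' @param seed optional integer seed for the deterministic jitter.
#' @param dt_h grid resolution, h.
#' @return an object of class `sglt_daily_profile`: tibble `time_h`,
#'   `glucose_mgdl`, with the achieved time-weighted mean as attribute
#'   `mean_mgdl`.
#' @examples
#' synth_daily_glucose_profile(90, 80, 125, seed = 1)
#' @export
synth_daily_glucose_profile <- function(mean_mgdl = 90, min_mgdl = 80,
                                        max_mgdl = 125,
                                        meal_times = c(7, 12, 18),
                                        seed = NULL, dt_h = 0.01) {
  if (min_mgdl > mean_mgdl || mean_mgdl > max_mgdl) {
    stop("need min_mgdl <= mean_mgdl <= max_mgdl", call. = FALSE)
  }
  tg <- seq(0, 24, by = dt_h)
  twmean <- function(v) {
    (sum(v) - (v[1] + v[length(v)]) / 2) / (length(v) - 1)
  }
  if (min_mgdl == max_mgdl) {
    out <- tibble::tibble(time_h = tg, glucose_mgdl = rep(mean_mgdl, length(tg)))
    attr(out, "mean_mgdl") <- mean_mgdl
    class(out) <- c("sglt_daily_profile", class(out))
    return(out)
  }
  amp_w <- rep(1, length(meal_times))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    meal_times <- meal_times + stats::runif(length(meal_times), -0.25, 0.25)
    amp_w <- 1 + stats::runif(length(meal_times), -0.05, 0.05)
  }
  span <- max_mgdl - min_mgdl
  # nocturnal plateau 2/45 above the floor, daytime baseline 2/15 above,
  # on the profile's own scale (82 and 86 mg/dL for the 80-125 default)
  base <- (min_mgdl + span * 2 / 45) +
    span * 4 / 45 * (stats::plogis((tg - 6.5) / 0.5) -
                     stats::plogis((tg - 22.5) / 0.5))
  bump1 <- function(t0) {
    ifelse(tg < t0, 0,
           ifelse(tg < t0 + 0.5, (tg - t0) / 0.5,
                  exp(-(tg - t0 - 0.5) / 1.0)))
  }
  excess <- Reduce(`+`, purrr::map2(meal_times, amp_w, ~ .y * bump1(.x)))
  s <- (mean_mgdl - twmean(base)) / twmean(excess)
  if (s < 0) {
    stop("mean_mgdl below the baseline plateau; infeasible profile",
         call. = FALSE)
  }
  v <- base + s * excess
  if (max(v) > max_mgdl + 1e-9 || min(v) < min_mgdl - 1e-9) {
    stop("profile leaves [min_mgdl, max_mgdl]; relax the constraints",
         call. = FALSE)
  }
  out <- tibble::tibble(time_h = tg, glucose_mgdl = v)
  attr(out, "mean_mgdl") <- twmean(v)
  attr(out, "seed") <- seed
  class(out) <- c("sglt_daily_profile", class(out))
  out
}

#' Per-step and cumulative urinary glucose excretion
#'
#' Integrates urinary glucose output over each clamp step window of a
#' simulation and reports grams per step plus the running total.
#'
#' @param sim an [simulate_tubule()] result covering the protocol span.
#' @param protocol an [make_shc_protocol()] protocol.
#' @return tibble: `step`, `target_mgdl`, `t_start_h`, `t_end_h`,
#'   `uge_g`, `uge_cum_g`, `filtered_g`.
#' @export
stepwise_uge <- function(sim, protocol) {
  stopifnot(inherits(sim, "sglt_simulation"),
            inherits(protocol, "sglt_protocol"))
  ts <- sim$timeseries
  if (min(ts$time) > min(protocol$t_start_h) + 1e-9 ||
      max(ts$time) < max(protocol$t_end_h) - 1e-9) {
    stop("simulation does not cover the protocol span", call. = FALSE)
  }
  at <- function(col, t) stats::approx(ts$time, ts[[col]], xout = t)$y
  uge_mmol <- at("glu_urine", protocol$t_end_h) -
    at("glu_urine", protocol$t_start_h)
  filt_mmol <- at("glu_filtered", protocol$t_end_h) -
    at("glu_filtered", protocol$t_start_h)
  dplyr::mutate(
    dplyr::select(tibble::as_tibble(protocol), "step", "target_mgdl",
                  "t_start_h", "t_end_h"),
    uge_g = mmol_to_g(uge_mmol),
    uge_cum_g = cumsum(.data$uge_g),
    filtered_g = mmol_to_g(filt_mmol)
  )
}
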
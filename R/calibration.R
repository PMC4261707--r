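#' Exclude records whose actual glucose strays from the group mean
#'
#' Clamp data are analysed as group means; individual steps where the
#' achieved plasma glucose deviated 25 % or more from the group mean are
#' dropped before calibration so outlying steps cannot distort the
#' parameter estimates.
#'
#' @param records tibble with actual and group-mean glucose columns.
#' @param tolerance relative deviation at or beyond which a record is
#'   excluded (default 0.25; the boundary itself is excluded).
#' @param actual,group_mean column names, mg/dL.
#' @return list with `records` (kept rows), `excluded` (dropped rows),
#'   `n_excluded` and `fraction_excluded`.
#' @export
exclude_deviant_points <- function(records, tolerance = 0.25,
                                   actual = "glucose_mgdl",
                                   group_mean = "target_mgdl") {
  if (!all(c(actual, group_mean) %in% names(records))) {
    stop("records must carry `", actual, "` and `", group_mean, "` columns",
         call. = FALSE)
  }
  if (any(is.na(records[[group_mean]]))) {
    stop("missing group means", call. = FALSE)
  }
  dev <- abs(records[[actual]] - records[[group_mean]]) / records[[group_mean]]
  keep <- dev < tolerance
  list(
    records = records[keep, , drop = FALSE],
    excluded = records[!keep, , drop = FALSE],
    n_excluded = sum(!keep),
    fraction_excluded = mean(!keep)
  )
}

# lean steady-state UGE solve (same math as steady_state_profile, no
# result assembly) -- the calibration hot path
steady_uge_mmol_h <- function(cglu_mm, gfr, qfrac, vmax_seg, km_seg, ki_seg,
                              fup, drug_nm) {
  q <- qfrac * gfr
  cd <- if (drug_nm > 0) fup * gfr * drug_nm / q else numeric(length(q))
  l_in <- gfr * cglu_mm
  for (j in seq_along(q)) {
    k_app <- km_seg[j] * (1 + cd[j] / ki_seg[j])
    b <- q[j] * k_app + vmax_seg[j] - l_in
    root <- (-b + sqrt(b^2 + 4 * q[j] * l_in * k_app)) / (2 * q[j])
    l_in <- q[j] * root
  }
  l_in
}

transporters_for_class <- function(theta, subject_class) {
  vmax2 <- if (subject_class == "t2dm") theta[["vmax2"]] else
    theta[["vmax2"]] * theta[["prop_healthy"]]
  sglt_transporters(subject_class,
                    vmax1_mmol_h = theta[["vmax1"]],
                    vmax2_mmol_h = vmax2,
                    km1_mm = theta[["km1"]],
                    km2_mm = theta[["km2"]])
}

#' Forward model: per-step clamp UGE at given parameters
#'
#' Predicts the urinary glucose excreted in each clamp step. Each step is
#' treated as its own clamped condition and solved with the analytic
#' steady state (`method = "steady_state"`, the calibration default:
#' steps are long relative to tubular transit, and the quasi-steady
#' accounting keeps the objective smooth and fast); `method = "ode"`
#' instead integrates each arm's full staircase and accounts urine per
#' window, including bladder washout transients.
#'
#' @param records dataset rows: `glucose_mgdl`, `gfr_l_per_h`,
#'   `kx_l_per_h`, `step_duration_h`, `drug_nm`, `subject_class` (and,
#'   for the ODE path, `step` order within `arm`).
#' @param theta named parameter vector: `vmax1`, `vmax2` (T2DM),
#'   `prop_healthy`, `km1`, `km2`, `ki2`.
#' @param inhibitor [sglt_inhibitor()] used for drug arms (its `ki2_nm`
#'   is overridden by `theta[["ki2"]]`).
#' @param physiology [sglt_physiology()].
#' @param method `"steady_state"` or `"ode"`.
#' @return numeric vector of per-record UGE, g.
#' @export
predict_stepwise_uge <- function(records, theta,
                                 inhibitor = sglt_inhibitor("dapagliflozin"),
                                 physiology = sglt_physiology(),
                                 method = c("steady_state", "ode")) {
  method <- match.arg(method)
  inh <- inhibitor
  inh$ki2_nm <- theta[["ki2"]]
  if (method == "steady_state") {
    qfrac <- 1 - physiology$flow_decrement * (1:9)
    out <- numeric(nrow(records))
    for (cls in unique(records$subject_class)) {
      idx <- which(records$subject_class == cls)
      tr <- transporters_for_class(theta, cls)
      vmax_seg <- c(rep(tr$vmax2_mmol_h / 6, 6), rep(tr$vmax1_mmol_h / 3, 3))
      km_seg <- c(rep(tr$km2_mm, 6), rep(tr$km1_mm, 3))
      ki_seg <- c(rep(inh$ki2_nm, 6), rep(inh$ki1_nm, 3))
      for (i in idx) {
        uge_rate <- steady_uge_mmol_h(
          mgdl_to_mm(records$glucose_mgdl[i]), records$gfr_l_per_h[i],
          qfrac, vmax_seg, km_seg, ki_seg,
          inh$free_fraction, records$drug_nm[i]
        )
        out[i] <- mmol_to_g(uge_rate * records$step_duration_h[i])
      }
    }
    return(out)
  }
  # ODE path: rebuild each arm's staircase and account urine per step
  out <- numeric(nrow(records))
  for (arm in unique(records$arm)) {
    rows <- which(records$arm == arm)
    rows <- rows[order(records$step[rows])]
    r <- records[rows, ]
    tr <- transporters_for_class(theta, r$subject_class[1])
    drug_on <- any(r$drug_nm > 0)
    geom <- build_geometry(physiology, tr, if (drug_on) inh else NULL)
    proto <- make_shc_protocol(
      r$glucose_mgdl, step_duration_h = r$step_duration_h,
      gfr_by_step = r$gfr_l_per_h, kx_by_step = r$kx_l_per_h,
      drug = if (drug_on) r$drug_nm[1] else NULL, inhibitor = inh
    )
    tt <- sort(unique(c(seq(0, max(proto$t_end_h), by = 0.02), proto$t_end_h)))
    sim <- simulate_tubule(geom, as_forcing(proto), tt)
    out[rows] <- stepwise_uge(sim, proto)$uge_g
  }
  out
}

#' Weighted least-squares objective for clamp calibration
#'
#' Sum of squared residuals between observed and model-predicted per-step
#' UGE over all arms, restricted to the clinically relevant glucose range
#' (records outside it are ignored). Simulation failures at a candidate
#' parameter set return a large finite penalty so the optimizer can move
#' on.
#'
#' @param theta named parameter vector (see [predict_stepwise_uge()]).
#' @param data a clamp UGE dataset (e.g. [synth_shc_uge_dataset()]).
#' @param glucose_range inclusion window for the actual plasma glucose,
#'   mg/dL.
#' @param weighting `"absolute"` (unit weights on gram residuals) or
#'   `"relative"` (residuals scaled by the observation).
#' @inheritParams predict_stepwise_uge
#' @return scalar loss.
#' @export
uge_objective <- function(theta, data, glucose_range = c(100, 400),
                          weighting = c("absolute", "relative"),
                          inhibitor = sglt_inhibitor("dapagliflozin"),
                          physiology = sglt_physiology(),
                          method = "steady_state") {
  r <- uge_residuals(theta, data, glucose_range, match.arg(weighting),
                     inhibitor, physiology, method)
  sum(r^2)
}

uge_residuals <- function(theta, data, glucose_range, weighting,
                          inhibitor, physiology, method) {
  keep <- data$glucose_mgdl >= glucose_range[1] &
    data$glucose_mgdl <= glucose_range[2]
  d <- data[keep, , drop = FALSE]
  tryCatch({
    pred <- predict_stepwise_uge(d, theta, inhibitor, physiology, method)
    res <- pred - d$uge_g
    if (weighting == "relative") res <- res / pmax(d$uge_g, 0.05)
    res
  }, error = function(e) rep(1e3, sum(keep)))
}

#' Calibrate transporter kinetics from step-wise clamp UGE
#'
#' Bounded Levenberg-Marquardt least squares (log-parameterized) from
#' literature starting points: SGLT1 capacity 14 mmol/h and T2DM SGLT2
#' capacity 126 mmol/h (10 %/90 % of a 140 mmol/h total), healthy SGLT2
#' capacity expressed as a proportion of the T2DM value (start 1.0),
#' glucose affinities 1.8/4.9 mM, and inhibitor SGLT2 affinity 6 nM. The
#' inhibitor affinity `ki2` is structurally non-identifiable without at
#' least one drug arm; in that case it is frozen at its starting value
#' and flagged. Optional seeded multi-start perturbs the starting point
#' log-uniformly within the bounds.
#'
#' @param data clamp UGE dataset (see [synth_shc_uge_dataset()] for the
#'   column schema).
#' @param start,lower,upper named numeric vectors over
#'   `c(vmax1, vmax2, prop_healthy, km1, km2, ki2)`.
#' @param glucose_range calibration window on actual glucose, mg/dL.
#' @param weighting see [uge_objective()].
#' @param n_starts number of optimization starts (the first is the
#'   stated starting point).
#' @param seed integer seed for the multi-start draws.
#' @inheritParams predict_stepwise_uge
#' @return an object of class `sglt_calibration`: `estimates` tibble,
#'   `loss`, `ki2_identifiable`, `fit` (best `nls.lm` object),
#'   `fitted` per-record predictions at the optimum, and inputs.
#' @export
calibrate_sglt <- function(data,
                           start = c(vmax1 = 14, vmax2 = 126,
                                     prop_healthy = 1.0, km1 = 1.8,
                                     km2 = 4.9, ki2 = 6),
                           lower = c(vmax1 = 1, vmax2 = 10,
                                     prop_healthy = 0.2, km1 = 0.05,
                                     km2 = 0.2, ki2 = 1e-3),
                           upper = c(vmax1 = 100, vmax2 = 400,
                                     prop_healthy = 1.5, km1 = 20,
                                     km2 = 50, ki2 = 1000),
                           glucose_range = c(100, 400),
                           weighting = c("absolute", "relative"),
                           n_starts = 1, seed = NULL,
                           inhibitor = sglt_inhibitor("dapagliflozin"),
                           physiology = sglt_physiology(),
                           method = "steady_state") {
  weighting <- match.arg(weighting)
  stopifnot(all(names(lower) == names(start)),
            all(names(upper) == names(start)),
            all(lower <= start & start <= upper))
  has_drug <- any(data$drug_nm > 0)
  has_healthy <- any(data$subject_class == "healthy")
  free <- names(start)
  if (!has_drug) free <- setdiff(free, "ki2")
  if (!has_healthy) free <- setdiff(free, "prop_healthy")
  if (!has_drug) {
    warning("no drug arm in the data: ki2 is structurally non-identifiable ",
            "and is held at its starting value; separation of vmax1/vmax2 ",
            "may be degraded", call. = FALSE)
  }

  full_theta <- function(logp) {
    th <- start
    th[free] <- exp(logp)
    th
  }
  resid_fun <- function(logp) {
    uge_residuals(full_theta(logp), data, glucose_range, weighting,
                  inhibitor, physiology, method)
  }

  starts <- list(log(start[free]))
  if (n_starts > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (k in seq_len(n_starts - 1)) {
      starts[[k + 1]] <- log(lower[free]) +
        stats::runif(length(free)) * (log(upper[free]) - log(lower[free]))
    }
  }
  best <- NULL
  for (s0 in starts) {
    fit <- minpack.lm::nls.lm(
      par = s0, fn = resid_fun,
      lower = log(lower[free]), upper = log(upper[free]),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    )
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (!best$info %in% 1:4) {
    warning("calibration did not converge (info = ", best$info,
            "); best-so-far parameters returned", call. = FALSE)
  }
  theta_hat <- full_theta(best$par)
  terms <- names(start)
  is_free <- terms %in% free
  estimates <- tibble::tibble(
    term = terms,
    estimate = unname(theta_hat[terms]),
    start = unname(start),
    lower = unname(lower),
    upper = unname(upper),
    free = is_free
  )
  keep <- data$glucose_mgdl >= glucose_range[1] &
    data$glucose_mgdl <= glucose_range[2]
  fitted <- data[keep, , drop = FALSE]
  fitted$uge_pred_g <- predict_stepwise_uge(fitted, theta_hat, inhibitor,
                                            physiology, method)
  structure(
    list(estimates = estimates, loss = sum(best$fvec^2), fit = best,
         converged = best$info %in% 1:4,
         ki2_identifiable = has_drug, fitted = fitted,
         glucose_range = glucose_range, weighting = weighting,
         method = method),
    class = "sglt_calibration"
  )
}

#' @export
print.sglt_calibration <- function(x, ...) {
  cat("<sglt_calibration>", if (x$converged) "converged" else "NOT converged",
      "| loss", format(x$loss, digits = 4),
      if (!x$ki2_identifiable) "| ki2 NOT identifiable (no drug arm)" else "",
      "\n")
  print(x$estimates)
  invisible(x)
}

#' @exportS3Method
#' @export
tidy.sglt_calibration <- function(x, ...) x$estimates

#' @exportS3Method
#' @export
glance.sglt_calibration <- function(x, ...) {
  tibble::tibble(
    loss = x$loss,
    converged = x$converged,
    ki2_identifiable = x$ki2_identifiable,
    n_obs = nrow(x$fitted),
    n_free = sum(x$estimates$free),
    n_iter = x$fit$niter
  )
}
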
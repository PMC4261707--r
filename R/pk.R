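#' Two-compartment pharmacokinetic model with repeated oral dosing
#'
#' Standard two-compartment disposition (central volume `vc`, peripheral
#' volume `vp`, inter-compartmental clearance `q`, elimination clearance
#' `cl`) with first-order oral absorption `ka`. Multiple once-daily (or
#' arbitrary-interval) doses are handled by superposition of the
#' single-dose solution, which approaches a periodic steady state.
#'
#' @param dose_mg dose per administration, mg.
#' @param ka_1_h first-order absorption rate constant, 1/h; `Inf` gives
#'   the IV-bolus (instantaneous absorption) limit.
#' @param cl_l_h elimination clearance, L/h.
#' @param vc_l central volume, L.
#' @param q_l_h inter-compartmental clearance, L/h.
#' @param vp_l peripheral volume, L.
#' @param interval_h dosing interval, h.
#' @param n_doses number of doses administered.
#' @param molecular_weight g/mol, used to express concentrations in nM.
#' @param bioavailability fraction of the dose absorbed.
#' @return an object of class `two_compartment_pk`.
#' @examples
#' two_compartment_pk(dose_mg = 100, ka_1_h = 1, cl_l_h = 12, vc_l = 50,
#'                    q_l_h = 10, vp_l = 70, n_doses = 8,
#'                    molecular_weight = 454)
#' @export
two_compartment_pk <- function(dose_mg, ka_1_h, cl_l_h, vc_l, q_l_h, vp_l,
                               interval_h = 24, n_doses = 1,
                               molecular_weight = 454,
                               bioavailability = 1) {
  stopifnot(dose_mg >= 0, ka_1_h > 0, cl_l_h > 0, vc_l > 0, q_l_h >= 0,
            vp_l > 0, interval_h > 0, n_doses >= 1, molecular_weight > 0,
            bioavailability > 0, bioavailability <= 1)
  structure(
    list(dose_mg = dose_mg, ka_1_h = ka_1_h, cl_l_h = cl_l_h, vc_l = vc_l,
         q_l_h = q_l_h, vp_l = vp_l, interval_h = interval_h,
         n_doses = n_doses, molecular_weight = molecular_weight,
         bioavailability = bioavailability),
    class = "two_compartment_pk"
  )
}

# hybrid rate constants of the two-compartment disposition
two_comp_macro <- function(model) {
  k10 <- model$cl_l_h / model$vc_l
  k12 <- model$q_l_h / model$vc_l
  k21 <- model$q_l_h / model$vp_l
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

# central concentration (mg/L) at time t after a single oral dose at t = 0
single_dose_conc <- function(model, t) {
  m <- two_comp_macro(model)
  ka <- model$ka_1_h
  d <- model$dose_mg * model$bioavailability
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  if (is.infinite(ka)) {
    # IV-bolus limit of instantaneous absorption
    if (model$q_l_h == 0) {
      out[pos] <- d / model$vc_l * exp(-m$k10 * tp)
    } else {
      out[pos] <- d / model$vc_l *
        ((m$alpha - m$k21) / (m$alpha - m$beta) * exp(-m$alpha * tp) +
         (m$k21 - m$beta) / (m$alpha - m$beta) * exp(-m$beta * tp))
    }
    return(out)
  }
  if (model$q_l_h == 0) {
    # one-compartment limit
    k10 <- m$k10
    out[pos] <- if (abs(ka - k10) < 1e-12) {
      d / model$vc_l * k10 * tp * exp(-k10 * tp)
    } else {
      d * ka / (model$vc_l * (ka - k10)) * (exp(-k10 * tp) - exp(-ka * tp))
    }
    return(out)
  }
  a <- (m$k21 - m$alpha) / ((ka - m$alpha) * (m$beta - m$alpha))
  b <- (m$k21 - m$beta) / ((ka - m$beta) * (m$alpha - m$beta))
  cc <- (m$k21 - ka) / ((m$alpha - ka) * (m$beta - ka))
  out[pos] <- d * ka / model$vc_l *
    (a * exp(-m$alpha * tp) + b * exp(-m$beta * tp) + cc * exp(-ka * tp))
  out
}

#' Sampled (empirical) plasma concentration profile
#'
#' Holds observed mean concentrations at sampling times; queried values
#' are piecewise-linear interpolations with flat extension beyond the
#' first/last sample (optional).
#'
#' @param time_h strictly increasing sampling times, h.
#' @param conc_ng_ml non-negative concentrations, ng/mL.
#' @param molecular_weight g/mol, for conversion to nM.
#' @param extrapolate if `FALSE`, querying outside the sampled span is an
#'   error; if `TRUE` (default) values are held flat at the edges.
#' @return an object of class `empirical_pk_profile`.
#' @export
empirical_pk_profile <- function(time_h, conc_ng_ml, molecular_weight = 409,
                                 extrapolate = TRUE) {
  if (length(time_h) == 0) stop("at least one sample required", call. = FALSE)
  stopifnot(length(time_h) == length(conc_ng_ml), all(conc_ng_ml >= 0),
            molecular_weight > 0)
  if (any(diff(time_h) <= 0)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(time_h = as.numeric(time_h), conc_ng_ml = as.numeric(conc_ng_ml),
         molecular_weight = molecular_weight, extrapolate = extrapolate),
    class = "empirical_pk_profile"
  )
}

#' Total plasma drug concentration at given times
#'
#' Evaluates a PK input as total plasma concentration in nM: either the
#' superposed multiple-dose two-compartment solution or linear
#' interpolation of an empirical profile.
#'
#' @param model a [two_compartment_pk()] or [empirical_pk_profile()].
#' @param t times, h (dosing starts at 0 for the model-based path).
#' @return numeric vector, nM.
#' @export
pk_concentration <- function(model, t) {
  UseMethod("pk_concentration")
}

#' @export
pk_concentration.two_compartment_pk <- function(model, t) {
  conc <- numeric(length(t))
  for (i in seq_len(model$n_doses)) {
    conc <- conc + single_dose_conc(model, t - (i - 1) * model$interval_h)
  }
  # mg/L -> nM: mg/L / (g/mol) * 1e6
  conc / model$molecular_weight * 1e6
}

#' @export
pk_concentration.empirical_pk_profile <- function(model, t) {
  if (!model$extrapolate &&
      (any(t < model$time_h[1]) || any(t > model$time_h[length(model$time_h)]))) {
    stop("query time outside the sampled span (set extrapolate = TRUE)",
         call. = FALSE)
  }
  ngml <- stats::approx(model$time_h, model$conc_ng_ml, xout = t, rule = 2)$y
  ngml / model$molecular_weight * 1000
}

#' Glomerular filtration rate of an inhibitor
#'
#' Only the unbound fraction of circulating drug is filtered:
#' `fup * GFR * C_plasma_total`.
#'
#' @param c_plasma_total_nm total plasma concentration, nM.
#' @param free_fraction unbound fraction in plasma.
#' @param gfr_l_per_h GFR, L/h.
#' @return filtration rate, nmol/h.
#' @examples
#' filtered_drug_rate(1000, 0.07, 6.5)  # 455 nmol/h
#' @export
filtered_drug_rate <- function(c_plasma_total_nm, free_fraction, gfr_l_per_h) {
  stopifnot(all(c_plasma_total_nm >= 0), free_fraction >= 0,
            free_fraction <= 1, gfr_l_per_h >= 0)
  free_fraction * gfr_l_per_h * c_plasma_total_nm
}

#' Fit a two-compartment model to sampled concentrations
#'
#' Least-squares fit on log-residuals (Levenberg-Marquardt via
#' `minpack.lm::nls.lm`, parameters estimated on the log scale so the
#' positivity constraints are built in). Requires at least five samples.
#'
#' @param samples an [empirical_pk_profile()].
#' @param init a [two_compartment_pk()] supplying starting values, the
#'   dosing regimen and the molecular weight (regimen and MW are held
#'   fixed; `ka`, `cl`, `vc`, `q`, `vp` are estimated).
#' @return an object of class `sglt_pk_fit`: list with `model` (fitted
#'   [two_compartment_pk()]), `fit` (the `nls.lm` object), `samples`, and
#'   `converged`.
#' @export
fit_two_compartment <- function(samples, init) {
  stopifnot(inherits(samples, "empirical_pk_profile"),
            inherits(init, "two_compartment_pk"))
  if (length(samples$time_h) < 5) {
    stop("at least 5 PK samples are required", call. = FALSE)
  }
  obs_nm <- samples$conc_ng_ml / samples$molecular_weight * 1000
  if (any(obs_nm <= 0)) {
    stop("log-residual fitting requires strictly positive concentrations",
         call. = FALSE)
  }
  make_model <- function(logp) {
    p <- exp(logp)
    two_compartment_pk(
      dose_mg = init$dose_mg, ka_1_h = p[["ka"]], cl_l_h = p[["cl"]],
      vc_l = p[["vc"]], q_l_h = p[["q"]], vp_l = p[["vp"]],
      interval_h = init$interval_h, n_doses = init$n_doses,
      molecular_weight = init$molecular_weight,
      bioavailability = init$bioavailability
    )
  }
  resid_fun <- function(logp) {
    pred <- pk_concentration(make_model(logp), samples$time_h)
    log(pmax(pred, 1e-12)) - log(obs_nm)
  }
  start <- log(c(ka = init$ka_1_h, cl = init$cl_l_h, vc = init$vc_l,
                 q = init$q_l_h, vp = init$vp_l))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("PK fit did not converge (info = ", fit$info,
            "); returning best-so-far parameters", call. = FALSE)
  }
  structure(
    list(model = make_model(fit$par), fit = fit, samples = samples,
         converged = converged),
    class = "sglt_pk_fit"
  )
}

#' @export
print.sglt_pk_fit <- function(x, ...) {
  cat("<sglt_pk_fit>", if (x$converged) "converged" else "NOT converged",
      "| RSS", format(sum(x$fit$fvec^2), digits = 4), "\n")
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method
#' @export
tidy.sglt_pk_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ka_1_h", "cl_l_h", "vc_l", "q_l_h", "vp_l"),
    estimate = c(x$model$ka_1_h, x$model$cl_l_h, x$model$vc_l,
                 x$model$q_l_h, x$model$vp_l)
  )
}

#' @exportS3Method
#' @export
glance.sglt_pk_fit <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    rss_log = sum(x$fit$fvec^2),
    n_samples = length(x$samples$time_h),
    n_iter = x$fit$niter
  )
}

#' Synthetic dapagliflozin-like day-profile (non-reference stand-in)
#'
#' A plausible steady-state (day 7) total plasma concentration profile for
#' 10 mg once-daily dosing of a dapagliflozin-like inhibitor, generated
#' from a one-compartment oral model (tmax about 1.3 h, terminal
#' half-life about 12 h, Cmax about 150 ng/mL). This is a synthetic
#' stand-in -- the original study's observed mean profile is not public --
#' and is intended for qualitative drug-arm demonstrations only.
#'
#' @param time_h sampling times over the dosing day, h.
#' @return an [empirical_pk_profile()] (MW 409).
#' @export
synthetic_dapagliflozin_profile <- function(time_h = c(0, 0.5, 1, 1.5, 2, 3,
                                                       4, 6, 8, 12, 16, 24)) {
  ka <- 2.0
  ke <- log(2) / 12
  v_f <- 100 # L, apparent volume
  dose <- 10 # mg
  acc <- 1 / (1 - exp(-ke * 24)) # once-daily accumulation at steady state
  conc_mg_l <- dose * ka / (v_f * (ka - ke)) *
    (exp(-ke * time_h) * acc - exp(-ka * time_h) / (1 - exp(-ka * 24)))
  empirical_pk_profile(time_h, pmax(conc_mg_l, 0) * 1000,
                       molecular_weight = 409)
}
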
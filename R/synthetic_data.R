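lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Synthetic four-arm stepped-clamp UGE dataset
#'
#' Emulates the design of a calibration clamp study: healthy and T2DM
#' subjects, each at baseline and under an SGLT2 inhibitor, stepped
#' through escalating plasma glucose targets. Per step, the achieved
#' glucose is jittered within +/- 5 % of the target, GFR is drawn
#' uniformly from the arm's registry range, UGE is computed from the
#' truth parameters by the forward model, and multiplicative lognormal
#' noise with coefficient of variation `noise_cv` (unit mean) is applied.
#' Fully deterministic given `seed`.
#'
#' @param truth named vector of true parameters
#'   (`vmax1`, `vmax2` T2DM, `prop_healthy`, `km1`, `km2`, `ki2`);
#'   defaults to the shipped registry values.
#' @param targets_mgdl per-step glucose targets, mg/dL.
#' @param step_duration_h step length, h.
#' @param drug_nm constant total plasma inhibitor concentration in the
#'   drug arms, nM; the default 245 nM (100 ng/mL) approximates the
#'   clamp-average total dapagliflozin exposure after 10 mg once daily.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param arms subset of arms to generate.
#' @param inhibitor,physiology,method forward-model inputs, see
#'   [predict_stepwise_uge()].
#' @return a tibble (class `sglt_uge_dataset`): `arm`, `subject_class`,
#'   `step`, `target_mgdl`, `glucose_mgdl` (actual), `gfr_l_per_h`,
#'   `kx_l_per_h`, `step_duration_h`, `drug_nm`, `uge_g`; the truth and
#'   noise settings are attached as attributes.
#' @examples
#' synth_shc_uge_dataset(noise_cv = 0, seed = 1)
#' @export
synth_shc_uge_dataset <- function(truth = c(vmax1 = 20, vmax2 = 110,
                                            prop_healthy = 93.5 / 110,
                                            km1 = 0.5, km2 = 4.0, ki2 = 0.3),
                                  targets_mgdl = seq(100, 550, by = 50),
                                  step_duration_h = 2 / 3,
                                  drug_nm = 245,
                                  noise_cv = 0.05, seed = 1,
                                  arms = c("healthy_baseline", "healthy_drug",
                                           "t2dm_baseline", "t2dm_drug"),
                                  inhibitor = sglt_inhibitor("dapagliflozin"),
                                  physiology = sglt_physiology(),
                                  method = "steady_state") {
  stopifnot(noise_cv >= 0)
  registry <- sglt_parameter_sets()$physiology
  set.seed(seed)
  n <- length(targets_mgdl)
  arm_tbl <- purrr::map_dfr(arms, function(a) {
    cls <- sub("_(baseline|drug)$", "", a)
    kind <- sub("^(healthy|t2dm)_", "", a)
    gfr_range <- registry$gfr_ranges_l_per_h[[paste0(cls, "_", kind)]]
    kx_range <- registry$urine_outflow_ranges_l_per_h[[paste0(cls, "_", kind)]]
    tibble::tibble(
      arm = a,
      subject_class = cls,
      step = seq_len(n),
      target_mgdl = targets_mgdl,
      glucose_mgdl = targets_mgdl * (1 + stats::runif(n, -0.05, 0.05)),
      gfr_l_per_h = stats::runif(n, gfr_range[1], gfr_range[2]),
      kx_l_per_h = mean(kx_range),
      step_duration_h = step_duration_h,
      drug_nm = if (kind == "drug") drug_nm else 0
    )
  })
  arm_tbl$uge_g <- predict_stepwise_uge(arm_tbl, truth, inhibitor,
                                        physiology, method) *
    lognormal_noise(nrow(arm_tbl), noise_cv)
  attr(arm_tbl, "truth") <- truth
  attr(arm_tbl, "noise_cv") <- noise_cv
  attr(arm_tbl, "seed") <- seed
  attr(arm_tbl, "method") <- method
  class(arm_tbl) <- c("sglt_uge_dataset", class(arm_tbl))
  arm_tbl
}

#' Synthetic sparse PK samples from a known two-compartment truth
#'
#' Evaluates a [two_compartment_pk()] model at the requested times and
#' applies multiplicative lognormal noise (unit mean, CV `noise_cv`),
#' returning an [empirical_pk_profile()] ready for [fit_two_compartment()]
#' recovery studies.
#'
#' @param truth a [two_compartment_pk()] model.
#' @param time_h strictly increasing, non-empty sampling times, h.
#' @param noise_cv coefficient of variation of the noise.
#' @param seed integer seed.
#' @return an [empirical_pk_profile()].
#' @export
synth_pk_samples <- function(truth, time_h, noise_cv = 0.1, seed = 1) {
  stopifnot(inherits(truth, "two_compartment_pk"), noise_cv >= 0)
  if (length(time_h) == 0) stop("`time_h` must be non-empty", call. = FALSE)
  set.seed(seed)
  conc_nm <- pk_concentration(truth, time_h)
  conc_ngml <- conc_nm * truth$molecular_weight / 1000 *
    lognormal_noise(length(time_h), noise_cv)
  empirical_pk_profile(time_h, conc_ngml,
                       molecular_weight = truth$molecular_weight)
}
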
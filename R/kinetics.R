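#' Michaelis-Menten glucose reabsorption rate in one sub-segment
#'
#' `R = Vmax * C / (Km + C)` for luminal glucose concentration `C`.
#' The rate is bounded by `Vmax` and monotone non-decreasing in `C`.
#'
#' @param vmax_mmol_h sub-segment transport capacity, mmol/h (> 0).
#' @param km_mm glucose affinity, mM (> 0).
#' @param c_glu_mm luminal glucose concentration, mM (>= 0); vectorised.
#' @return reabsorption rate, mmol/h.
#' @examples
#' reabsorption_rate(15.583, 4, 4)  # half saturation: Vmax/2
#' @export
reabsorption_rate <- function(vmax_mmol_h, km_mm, c_glu_mm) {
  stopifnot(all(vmax_mmol_h > 0), all(km_mm > 0))
  if (any(c_glu_mm < 0)) {
    stop("glucose concentration must be non-negative", call. = FALSE)
  }
  vmax_mmol_h * c_glu_mm / (km_mm + c_glu_mm)
}

#' Reabsorption rate under competitive inhibition
#'
#' A luminal inhibitor competing with glucose for the transporter scales
#' the apparent affinity: `R = Vmax * C / (Km * (1 + D / Ki) + C)` for
#' luminal drug concentration `D`. With `D = 0` this is exactly the
#' uninhibited Michaelis-Menten rate; as `D` grows the rate falls
#' monotonically toward zero.
#'
#' @inheritParams reabsorption_rate
#' @param c_drug_nm luminal inhibitor concentration, nM (>= 0).
#' @param ki_nm inhibitor affinity for the transporter, nM (> 0).
#' @return reabsorption rate, mmol/h.
#' @examples
#' inhibited_reabsorption_rate(15.583, 4, 4, c_drug_nm = 0.3, ki_nm = 0.3)
#' @export
inhibited_reabsorption_rate <- function(vmax_mmol_h, km_mm, c_glu_mm,
                                        c_drug_nm, ki_nm) {
  stopifnot(all(vmax_mmol_h > 0), all(km_mm > 0), all(ki_nm > 0))
  if (any(c_glu_mm < 0)) {
    stop("glucose concentration must be non-negative", call. = FALSE)
  }
  if (any(c_drug_nm < 0)) {
    stop("drug concentration must be non-negative", call. = FALSE)
  }
  vmax_mmol_h * c_glu_mm / (km_mm * (1 + c_drug_nm / ki_nm) + c_glu_mm)
}
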
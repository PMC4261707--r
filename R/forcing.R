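as_time_fun <- function(x) {
  if (is.function(x)) return(x)
  stopifnot(is.numeric(x), length(x) == 1)
  force(x)
  function(t) rep_len(x, length(t))
}

#' Time-varying boundary conditions for a tubule simulation
#'
#' A forcing bundles the plasma glucose concentration, total plasma
#' inhibitor concentration, GFR and urine outflow as functions of time.
#' Plasma glucose is always an input (clamped or profiled), never a model
#' state: reabsorbed glucose is routed to an accumulator, not back to
#' plasma. `breaks` lists interior discontinuity times (e.g. clamp step
#' boundaries); the integrator restarts there.
#'
#' @param cglu_mm plasma glucose, mM: a constant or a function of time (h).
#' @param gfr_l_per_h GFR, L/h: constant or function of time.
#' @param kx_l_per_h urine outflow, L/h: constant or function of time.
#' @param cdrug_nm total plasma inhibitor concentration, nM: constant or
#'   function of time (0 when no drug).
#' @param breaks numeric vector of discontinuity times, h.
#' @return an object of class `sglt_forcing`.
#' @examples
#' sglt_forcing(cglu_mm = convert_units(100, "mg/dL", "mM"),
#'              gfr_l_per_h = 6.5, kx_l_per_h = 0.6)
#' @export
sglt_forcing <- function(cglu_mm, gfr_l_per_h, kx_l_per_h,
                         cdrug_nm = 0, breaks = numeric(0)) {
  structure(
    list(
      cglu_mm = as_time_fun(cglu_mm),
      cdrug_nm = as_time_fun(cdrug_nm),
      gfr_l_per_h = as_time_fun(gfr_l_per_h),
      kx_l_per_h = as_time_fun(kx_l_per_h),
      breaks = sort(unique(breaks))
    ),
    class = "sglt_forcing"
  )
}

#' Constant-condition forcing
#'
#' Convenience wrapper for clamped runs: constant plasma glucose (mg/dL at
#' the interface), constant GFR, urine outflow and, optionally, constant
#' total plasma drug concentration.
#'
#' @param glucose_mgdl plasma glucose, mg/dL.
#' @param gfr_l_per_h GFR, L/h.
#' @param kx_l_per_h urine outflow, L/h.
#' @param drug_nm total plasma inhibitor concentration, nM.
#' @return an `sglt_forcing` object.
#' @export
forcing_constant <- function(glucose_mgdl, gfr_l_per_h, kx_l_per_h = 0.6,
                             drug_nm = 0) {
  stopifnot(glucose_mgdl >= 0, gfr_l_per_h > 0, kx_l_per_h > 0, drug_nm >= 0)
  sglt_forcing(
    cglu_mm = mgdl_to_mm(glucose_mgdl),
    gfr_l_per_h = gfr_l_per_h,
    kx_l_per_h = kx_l_per_h,
    cdrug_nm = drug_nm
  )
}
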
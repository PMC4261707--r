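#' Build the nine-sub-segment tubule geometry
#'
#' Divides the proximal convoluted tubule into six equal sub-segments
#' (PCT1-6, carrying SGLT2) and the proximal straight tubule into three
#' (PST1-3, carrying SGLT1). Luminal flow out of sub-segment *i* is
#' `(1 - flow_decrement * i) * GFR`: water reabsorption removes the same
#' fraction of GFR in every sub-segment, so roughly two thirds of filtered
#' water is gone by the end of the proximal tubule. Transporter capacity
#' is split uniformly: `vmax2 / 6` per PCT sub-segment, `vmax1 / 3` per
#' PST sub-segment.
#'
#' @param physiology an [sglt_physiology()] object.
#' @param transporters an [sglt_transporters()] object.
#' @param inhibitor optional [sglt_inhibitor()]; fills the per-segment
#'   `ki_nm` column (SGLT2 affinity in PCT, SGLT1 affinity in PST). When
#'   absent, `ki_nm` is `Inf` so the inhibition term vanishes identically.
#' @return a tibble with one row per sub-segment:
#'   `segment`, `kind` (`"PCT"`/`"PST"`), `transporter`, `volume_l`,
#'   `outflow_l_per_h`, `vmax_mmol_h`, `km_mm`, `ki_nm`; physiology is
#'   attached as attributes `gfr`, `kx`, `bladder_volume`, `free_fraction`.
#' @examples
#' build_geometry(sglt_physiology(), sglt_transporters("healthy"))
#' @export
build_geometry <- function(physiology, transporters, inhibitor = NULL) {
  stopifnot(inherits(physiology, "sglt_physiology"),
            inherits(transporters, "sglt_transporters"))
  if (!is.null(inhibitor) && !inherits(inhibitor, "sglt_inhibitor")) {
    stop("`inhibitor` must be an sglt_inhibitor object", call. = FALSE)
  }
  pt_volume <- physiology$renal_cortex_volume_l * physiology$pt_fraction_of_cortex
  pct_volume <- pt_volume * physiology$pct_fraction_of_pt
  pst_volume <- pt_volume * (1 - physiology$pct_fraction_of_pt)
  kind <- c(rep("PCT", 6), rep("PST", 3))
  geom <- tibble::tibble(
    segment = c(paste0("PCT", 1:6), paste0("PST", 1:3)),
    kind = kind,
    transporter = ifelse(kind == "PCT", "SGLT2", "SGLT1"),
    volume_l = c(rep(pct_volume / 6, 6), rep(pst_volume / 3, 3)),
    outflow_l_per_h = (1 - physiology$flow_decrement * (1:9)) *
      physiology$gfr_l_per_h,
    vmax_mmol_h = c(rep(transporters$vmax2_mmol_h / 6, 6),
                    rep(transporters$vmax1_mmol_h / 3, 3)),
    km_mm = c(rep(transporters$km2_mm, 6), rep(transporters$km1_mm, 3)),
    ki_nm = if (is.null(inhibitor)) rep(Inf, 9) else
      c(rep(inhibitor$ki2_nm, 6), rep(inhibitor$ki1_nm, 3))
  )
  attr(geom, "gfr") <- physiology$gfr_l_per_h
  attr(geom, "flow_fractions") <- 1 - physiology$flow_decrement * (1:9)
  attr(geom, "kx") <- physiology$urine_outflow_l_per_h
  attr(geom, "bladder_volume") <- physiology$bladder_volume_l
  attr(geom, "free_fraction") <- if (is.null(inhibitor)) 0 else
    inhibitor$free_fraction
  attr(geom, "inhibitor") <- inhibitor
  class(geom) <- c("sglt_geometry", class(geom))
  geom
}
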
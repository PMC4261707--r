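#' Load the shipped parameter registry
#'
#' The registry holds the default human physiology (cortex and tubule
#' volumes, flow scheme, per-arm GFR and urine-outflow ranges), transporter
#' kinetic sets for healthy and type-2-diabetic (T2DM) subjects, and
#' inhibitor-specific parameters for dapagliflozin and canagliflozin.
#'
#' @return a nested list mirroring `inst/extdata/parameter_sets.json`.
#' @export
sglt_parameter_sets <- function() {
  path <- system.file("extdata", "parameter_sets.json", package = "sgltsim")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Renal physiology parameters
#'
#' Volumes and flows of the modelled kidney: renal cortex volume, the
#' fraction occupied by proximal tubules (PT), the split of PT volume
#' between convoluted (PCT) and straight (PST) portions, bladder volume,
#' glomerular filtration rate (GFR), urine outflow, and the per-segment
#' luminal flow decrement (water reabsorption; each of the nine
#' sub-segments removes the same fraction of GFR so that luminal flow
#' falls from 0.926 x GFR after the first sub-segment to about
#' 0.334 x GFR after the last).
#'
#' @param gfr_l_per_h glomerular filtration rate, L/h.
#' @param urine_outflow_l_per_h flow out of the urinary bladder, L/h.
#' @param renal_cortex_volume_l cortex volume, L.
#' @param pt_fraction_of_cortex PT volume as fraction of cortex.
#' @param pct_fraction_of_pt PCT volume as fraction of PT (PST gets the
#'   remainder).
#' @param bladder_volume_l urinary bladder volume, L.
#' @param flow_decrement fraction of GFR removed as water per sub-segment.
#' @return an object of class `sglt_physiology` (a named list).
#' @examples
#' sglt_physiology(gfr_l_per_h = 6.5)
#' @export
sglt_physiology <- function(gfr_l_per_h = 6.5,
                            urine_outflow_l_per_h = 0.6,
                            renal_cortex_volume_l = 0.216,
                            pt_fraction_of_cortex = 0.3,
                            pct_fraction_of_pt = 0.7,
                            bladder_volume_l = 0.2,
                            flow_decrement = 0.074) {
  stopifnot(
    gfr_l_per_h > 0, urine_outflow_l_per_h > 0,
    renal_cortex_volume_l > 0, bladder_volume_l > 0,
    pt_fraction_of_cortex > 0, pt_fraction_of_cortex < 1,
    pct_fraction_of_pt > 0, pct_fraction_of_pt < 1,
    flow_decrement > 0, flow_decrement * 9 < 1
  )
  structure(
    list(
      gfr_l_per_h = gfr_l_per_h,
      urine_outflow_l_per_h = urine_outflow_l_per_h,
      renal_cortex_volume_l = renal_cortex_volume_l,
      pt_fraction_of_cortex = pt_fraction_of_cortex,
      pct_fraction_of_pt = pct_fraction_of_pt,
      bladder_volume_l = bladder_volume_l,
      flow_decrement = flow_decrement
    ),
    class = "sglt_physiology"
  )
}

#' Transporter kinetic parameters
#'
#' Maximal reabsorption capacities and glucose affinities of SGLT1
#' (high affinity, low capacity; PST) and SGLT2 (low affinity, high
#' capacity; PCT). The shipped sets differ only in SGLT2 capacity:
#' 93.5 mmol/h in healthy subjects versus 110 mmol/h in T2DM, reflecting
#' up-regulated SGLT2 activity in the diabetic state.
#'
#' @param subject_class `"healthy"` or `"t2dm"` to load a shipped set.
#' @param vmax1_mmol_h,vmax2_mmol_h SGLT1/SGLT2 whole-kidney capacity,
#'   mmol/h. Capacity is split uniformly across the three PST
#'   (respectively six PCT) sub-segments.
#' @param km1_mm,km2_mm glucose affinity (Michaelis constant) of
#'   SGLT1/SGLT2, mM.
#' @return an object of class `sglt_transporters`.
#' @examples
#' sglt_transporters("t2dm")
#' sglt_transporters("healthy", vmax2_mmol_h = 0)  # complete SGLT2 loss
#' @export
sglt_transporters <- function(subject_class = c("healthy", "t2dm"),
                              vmax1_mmol_h = NULL, vmax2_mmol_h = NULL,
                              km1_mm = NULL, km2_mm = NULL) {
  subject_class <- match.arg(subject_class)
  defaults <- sglt_parameter_sets()$transporters[[subject_class]]
  out <- list(
    vmax1_mmol_h = vmax1_mmol_h %||% defaults$vmax1_mmol_h,
    vmax2_mmol_h = vmax2_mmol_h %||% defaults$vmax2_mmol_h,
    km1_mm = km1_mm %||% defaults$km1_mm,
    km2_mm = km2_mm %||% defaults$km2_mm,
    subject_class = subject_class
  )
  stopifnot(
    out$vmax1_mmol_h >= 0, out$vmax2_mmol_h >= 0,
    out$km1_mm > 0, out$km2_mm > 0
  )
  structure(out, class = "sglt_transporters")
}

#' SGLT inhibitor parameters
#'
#' Physicochemical and binding parameters of an SGLT2 inhibitor: molecular
#' weight, free (unbound, hence filterable) fraction in plasma, and
#' competitive-inhibition affinities for SGLT1 (`ki1_nm`) and SGLT2
#' (`ki2_nm`). Shipped drugs: `"dapagliflozin"` and `"canagliflozin"`.
#'
#' @param name a shipped drug name, or any label when all parameters are
#'   supplied explicitly.
#' @param molecular_weight g/mol.
#' @param free_fraction unbound fraction in plasma, in (0, 1].
#' @param ki1_nm,ki2_nm affinity for SGLT1/SGLT2, nM.
#' @return an object of class `sglt_inhibitor`.
#' @examples
#' sglt_inhibitor("dapagliflozin")
#' @export
sglt_inhibitor <- function(name = c("dapagliflozin", "canagliflozin"),
                           molecular_weight = NULL, free_fraction = NULL,
                           ki1_nm = NULL, ki2_nm = NULL) {
  registry <- sglt_parameter_sets()$inhibitors
  if (is.character(name) && length(name) == 1 && name %in% names(registry)) {
    defaults <- registry[[name]]
  } else if (is.null(molecular_weight) || is.null(free_fraction) ||
             is.null(ki1_nm) || is.null(ki2_nm)) {
    name <- match.arg(name)
    defaults <- registry[[name]]
  } else {
    defaults <- list()
  }
  out <- list(
    name = name,
    molecular_weight = molecular_weight %||% defaults$molecular_weight,
    free_fraction = free_fraction %||% defaults$free_fraction,
    ki1_nm = ki1_nm %||% defaults$ki1_nm,
    ki2_nm = ki2_nm %||% defaults$ki2_nm
  )
  if (is.null(out$ki1_nm) || is.null(out$ki2_nm)) {
    stop("inhibitor must define an affinity (K_i) for both SGLT1 and SGLT2",
         call. = FALSE)
  }
  stopifnot(
    out$molecular_weight > 0,
    out$free_fraction > 0, out$free_fraction <= 1,
    out$ki1_nm > 0, out$ki2_nm > 0
  )
  structure(out, class = "sglt_inhibitor")
}

#' @export
print.sglt_physiology <- function(x, ...) {
  cat("<sglt_physiology> GFR", x$gfr_l_per_h, "L/h, urine outflow",
      x$urine_outflow_l_per_h, "L/h\n")
  invisible(x)
}

#' @export
print.sglt_transporters <- function(x, ...) {
  cat("<sglt_transporters>", x$subject_class,
      sprintf("| SGLT1: Vmax %.3g mmol/h, Km %.3g mM | SGLT2: Vmax %.3g mmol/h, Km %.3g mM\n",
              x$vmax1_mmol_h, x$km1_mm, x$vmax2_mmol_h, x$km2_mm))
  invisible(x)
}

#' @export
print.sglt_inhibitor <- function(x, ...) {
  cat("<sglt_inhibitor>", x$name,
      sprintf("| MW %.4g, fup %.3g, Ki1 %.4g nM, Ki2 %.3g nM\n",
              x$molecular_weight, x$free_fraction, x$ki1_nm, x$ki2_nm))
  invisible(x)
}
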
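#' Molecular weight of D-glucose (g/mol)
#'
#' Used for all glucose mass/concentration conversions.
#' @export
GLUCOSE_MW <- 180.16

#' Convert between the units used at the model interface
#'
#' Supported conversions: glucose `mg/dL` <-> `mM`, glucose `mmol` <-> `g`,
#' and drug `ng/mL` <-> `nM` (which require `mw`, the drug molecular weight
#' in g/mol). Conversions are exact linear maps.
#'
#' @param value numeric vector to convert.
#' @param from,to unit labels; one of `"mg/dL"`, `"mM"`, `"mmol"`, `"g"`,
#'   `"ng/mL"`, `"nM"`.
#' @param mw molecular weight in g/mol; defaults to glucose
#'   ([GLUCOSE_MW]). Pass the inhibitor MW for drug conversions.
#' @return numeric vector in the target units.
#' @examples
#' convert_units(100, "mg/dL", "mM")      # 5.551 mM
#' convert_units(1, "mmol", "g")          # 0.18016 g
#' convert_units(409, "ng/mL", "nM", mw = 409)  # 1000 nM
#' @export
convert_units <- function(value, from, to, mw = GLUCOSE_MW) {
  stopifnot(is.numeric(value), is.numeric(mw), mw > 0)
  pair <- paste(from, to, sep = "->")
  switch(pair,
    "mg/dL->mM" = value * 10 / mw,
    "mM->mg/dL" = value * mw / 10,
    "mmol->g"   = value * mw / 1000,
    "g->mmol"   = value * 1000 / mw,
    # ng/mL -> nmol/L: (ng/mL) / (g/mol) * 1000
    "ng/mL->nM" = value / mw * 1000,
    "nM->ng/mL" = value * mw / 1000,
    stop("unsupported unit conversion: ", from, " -> ", to, call. = FALSE)
  )
}

mgdl_to_mm <- function(x) x * 10 / GLUCOSE_MW
mm_to_mgdl <- function(x) x * GLUCOSE_MW / 10
mmol_to_g <- function(x) x * GLUCOSE_MW / 1000
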
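#' Analytic steady-state profile under clamped conditions
#'
#' For constant plasma glucose, drug, GFR and urine outflow, the tubule
#' reaches a steady state that can be solved segment by segment without
#' numerical integration. Writing the solute inflow of sub-segment *j* as
#' `L_in` (mmol/h), the mass balance `L_in = Q_j C_j + R_j(C_j)` with the
#' (possibly inhibited) Michaelis-Menten rate gives the quadratic
#' `Q_j C^2 + (Q_j K_app + Vmax_j - L_in) C - L_in K_app = 0`,
#' `K_app = Km (1 + C_drug_j / Ki)`, whose unique positive root is the
#' luminal glucose concentration. The drug, filtered at `fup * GFR *
#' C_plasma_drug` and not reabsorbed, has steady luminal concentration
#' `fup * GFR * C_plasma_drug / Q_j`, which rises monotonically along the
#' tubule as water is removed. This solver is the independent oracle for
#' the ODE integrator and the forward model for per-step clamp accounting.
#'
#' @param geometry an [build_geometry()] tibble.
#' @param glucose_mgdl constant plasma glucose, mg/dL.
#' @param drug_nm constant total plasma inhibitor concentration, nM.
#' @param gfr_l_per_h GFR, L/h; defaults to the geometry's physiology.
#' @param free_fraction unbound drug fraction; defaults to the geometry's
#'   inhibitor (0 when none).
#' @return an object of class `sglt_steady_state`: a list with
#'   `segments` (tibble: per-segment inflow, concentrations, rate,
#'   outflow) and scalar summaries (`filtered_mmol_h`, `sglt1_mmol_h`,
#'   `sglt2_mmol_h`, `uge_mmol_h`, `share_sglt2`, `efficiency_sglt1`,
#'   `efficiency_sglt2`, conditions).
#' @examples
#' geom <- build_geometry(sglt_physiology(), sglt_transporters("healthy"))
#' steady_state_profile(geom, glucose_mgdl = 100)
#' @export
steady_state_profile <- function(geometry, glucose_mgdl, drug_nm = 0,
                                 gfr_l_per_h = attr(geometry, "gfr"),
                                 free_fraction = attr(geometry, "free_fraction")) {
  stopifnot(inherits(geometry, "sglt_geometry"),
            glucose_mgdl >= 0, drug_nm >= 0, gfr_l_per_h > 0)
  if (drug_nm > 0 && (is.null(free_fraction) || free_fraction == 0)) {
    stop("drug forcing supplied but geometry carries no inhibitor", call. = FALSE)
  }
  q <- attr(geometry, "flow_fractions") * gfr_l_per_h
  cglu <- mgdl_to_mm(glucose_mgdl)
  filtered_drug <- free_fraction * gfr_l_per_h * drug_nm
  c_drug <- filtered_drug / q  # nM; increasing along the tubule

  n <- nrow(geometry)
  c_glu <- rate <- inflow <- numeric(n)
  l_in <- gfr_l_per_h * cglu
  for (j in seq_len(n)) {
    k_app <- geometry$km_mm[j] * (1 + c_drug[j] / geometry$ki_nm[j])
    a <- q[j]
    b <- q[j] * k_app + geometry$vmax_mmol_h[j] - l_in
    cc <- -l_in * k_app
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no real root in steady-state solve", call. = FALSE)
    root <- (-b + sqrt(disc)) / (2 * a)
    if (root < 0) stop("no positive root in steady-state solve", call. = FALSE)
    inflow[j] <- l_in
    c_glu[j] <- root
    rate[j] <- if (geometry$vmax_mmol_h[j] > 0) {
      inhibited_reabsorption_rate(geometry$vmax_mmol_h[j], geometry$km_mm[j],
                                  root, c_drug[j], geometry$ki_nm[j])
    } else 0
    l_in <- q[j] * root
  }

  segments <- dplyr::mutate(
    dplyr::select(geometry, "segment", "kind", "transporter", "volume_l",
                  "vmax_mmol_h", "km_mm", "ki_nm"),
    outflow_l_per_h = q,
    inflow_mmol_h = inflow,
    c_glu_mm = c_glu,
    c_drug_nm = c_drug,
    rate_mmol_h = rate,
    outflow_mmol_h = q * c_glu
  )

  is_pct <- geometry$kind == "PCT"
  vmax2 <- sum(geometry$vmax_mmol_h[is_pct])
  vmax1 <- sum(geometry$vmax_mmol_h[!is_pct])
  sglt2 <- sum(rate[is_pct])
  sglt1 <- sum(rate[!is_pct])
  total <- sglt1 + sglt2
  structure(
    list(
      segments = segments,
      glucose_mgdl = glucose_mgdl,
      drug_nm = drug_nm,
      free_fraction = free_fraction %||% 0,
      gfr_l_per_h = gfr_l_per_h,
      filtered_mmol_h = gfr_l_per_h * cglu,
      sglt1_mmol_h = sglt1,
      sglt2_mmol_h = sglt2,
      uge_mmol_h = l_in,
      share_sglt1 = if (total > 0) sglt1 / total else NA_real_,
      share_sglt2 = if (total > 0) sglt2 / total else NA_real_,
      efficiency_sglt1 = if (vmax1 > 0) sglt1 / vmax1 else NA_real_,
      efficiency_sglt2 = if (vmax2 > 0) sglt2 / vmax2 else NA_real_
    ),
    class = "sglt_steady_state"
  )
}

#' @export
print.sglt_steady_state <- function(x, ...) {
  cat(sprintf(
    "<sglt_steady_state> glucose %.4g mg/dL, GFR %.3g L/h, drug %.4g nM\n",
    x$glucose_mgdl, x$gfr_l_per_h, x$drug_nm))
  cat(sprintf(
    "  filtered %.4g mmol/h | SGLT2 %.4g | SGLT1 %.4g | UGE %.4g mmol/h\n",
    x$filtered_mmol_h, x$sglt2_mmol_h, x$sglt1_mmol_h, x$uge_mmol_h))
  invisible(x)
}

#' @importFrom generics tidy
#' @exportS3Method
#' @export
tidy.sglt_steady_state <- function(x, ...) x$segments

#' @importFrom generics glance
#' @exportS3Method
#' @export
glance.sglt_steady_state <- function(x, ...) {
  tibble::tibble(
    glucose_mgdl = x$glucose_mgdl,
    drug_nm = x$drug_nm,
    gfr_l_per_h = x$gfr_l_per_h,
    filtered_mmol_h = x$filtered_mmol_h,
    sglt1_mmol_h = x$sglt1_mmol_h,
    sglt2_mmol_h = x$sglt2_mmol_h,
    uge_mmol_h = x$uge_mmol_h,
    share_sglt1 = x$share_sglt1,
    share_sglt2 = x$share_sglt2,
    efficiency_sglt1 = x$efficiency_sglt1,
    efficiency_sglt2 = x$efficiency_sglt2
  )
}
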
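#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a steady-state axial profile
#'
#' Luminal glucose concentration and reabsorption rate along the nine
#' sub-segments at the clamped condition.
#'
#' @param object an `sglt_steady_state`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
#' @export
autoplot.sglt_steady_state <- function(object, ...) {
  seg <- object$segments
  seg$segment <- factor(seg$segment, levels = seg$segment)
  long <- tidyr::pivot_longer(
    seg[c("segment", "kind", "c_glu_mm", "rate_mmol_h")],
    c("c_glu_mm", "rate_mmol_h"),
    names_to = "quantity", values_to = "value"
  )
  labs <- c(c_glu_mm = "luminal glucose (mM)",
            rate_mmol_h = "reabsorption rate (mmol/h)")
  long$quantity <- labs[long$quantity]
  ggplot2::ggplot(long, ggplot2::aes(.data$segment, .data$value,
                                     fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = NULL,
      title = sprintf("Steady state at %.0f mg/dL plasma glucose",
                      object$glucose_mgdl)
    ) +
    ggplot2::theme_minimal()
}

#' Plot simulated urinary glucose and plasma forcing over time
#'
#' @param object an `sglt_simulation`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
#' @export
autoplot.sglt_simulation <- function(object, ...) {
  ts <- object$timeseries
  df <- tibble::tibble(
    time = rep(ts$time, 2),
    value = c(mm_to_mgdl(ts$plasma_glucose_mm),
              mmol_to_g(ts$glu_urine - ts$glu_urine[1])),
    quantity = rep(c("plasma glucose (mg/dL)", "cumulative UGE (g)"),
                   each = nrow(ts))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a loss-of-function scan
#'
#' Daily UGE and percent reduction in reabsorption against the lost
#' capacity fraction.
#'
#' @param object an `sglt_lof_scan` from [loss_of_function_scan()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
#' @export
autoplot.sglt_lof_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("fraction", "uge_g", "reduction_pct")],
    c("uge_g", "reduction_pct"),
    names_to = "quantity", values_to = "value"
  )
  labs <- c(uge_g = "UGE (g/day)",
            reduction_pct = "reabsorption reduction (%)")
  df$quantity <- labs[df$quantity]
  ggplot2::ggplot(df, ggplot2::aes(.data$fraction, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = sprintf("%s capacity lost (fraction)",
                  toupper(attr(object, "transporter") %||% "")),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a daily glucose profile
#'
#' @param object an `sglt_daily_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
#' @export
autoplot.sglt_daily_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_h, .data$glucose_mgdl)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "mean_mgdl"),
                        linetype = "dashed") +
    ggplot2::labs(x = "time (h)", y = "plasma glucose (mg/dL)") +
    ggplot2::theme_minimal()
}

#' Observed versus fitted per-step UGE of a calibration
#'
#' @param object an `sglt_calibration`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
#' @export
autoplot.sglt_calibration <- function(object, ...) {
  ggplot2::ggplot(object$fitted,
                  ggplot2::aes(.data$uge_g, .data$uge_pred_g,
                               colour = .data$arm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed UGE (g/step)", y = "fitted UGE (g/step)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
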
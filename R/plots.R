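map_plot_df <- function(values) {
  tibble(row = rep(seq_len(nrow(values)), ncol(values)),
         col = rep(seq_len(ncol(values)), each = nrow(values)),
         value = as.numeric(values))
}

#' Plot a contrast map
#'
#' Raster display of K with a fixed `[0, 1]` fill range (speckle contrast of
#' fully developed speckle cannot exceed 1, so maps stay comparable across
#' exposures and schemes).
#'
#' @param object A `contrast_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contrast_map <- function(object, ...) {
  df <- map_plot_df(object$K)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), oob = scales_squish,
                                  na.value = "grey20", name = "K") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s contrast, T = %.3g ms",
                                  object$scheme, 1e3 * object$exposure_T),
                  x = NULL, y = NULL)
}

scales_squish <- function(x, range = c(0, 1)) pmin(range[2], pmax(range[1], x))

#' Plot an inverse decorrelation-time map
#' @param object An `inv_tau_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.inv_tau_map <- function(object, ...) {
  df <- map_plot_df(object$inv_tau)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20",
                                  name = expression(1 / tau[c] ~ (s^-1))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a multi-exposure fit
#'
#' Observed ROI-mean K^2 against exposure with the fitted speckle correlation
#' model overlaid on a log exposure axis.
#'
#' @param object A `mesi_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mesi_fit <- function(object, ...) {
  s <- object$series
  grid <- exp(seq(log(min(s$exposure_s) / 2), log(max(s$exposure_s) * 2),
                  length.out = 200))
  curve_df <- tibble(exposure_s = grid,
                     k_squared = model_k_squared(grid, params = object$params))
  ggplot2::ggplot(s, ggplot2::aes(x = 1e3 * .data$exposure_s,
                                  y = .data$k_squared)) +
    ggplot2::geom_line(data = curve_df, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Exposure (ms)", y = expression(K^2),
                  title = sprintf("tau_c = %.3g ms",
                                  1e3 * object$params$tau_c))
}

#' Plot a vessel cross-section profile with its parabola fit
#' @param object A `cross_section`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cross_section <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Position along section (px)",
                  y = expression(1 / tau[c] ~ (s^-1)))
  if (!isTRUE(object$degenerate)) {
    cf <- object$parabola_coeffs
    fitted <- tibble(position = object$profile$position,
                     value = cf["a"] * object$profile$position^2 +
                       cf["b"] * object$profile$position + cf["c"])
    p <- p + ggplot2::geom_line(data = fitted, colour = "firebrick")
  }
  p
}

#' Plot per-frame motion QC metrics
#' @param object A `qc_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qc_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$frame, y = .data$metric,
                               colour = .data$retained)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold_used,
                        linetype = "dashed") +
    ggplot2::labs(x = "Frame", y = "Whole-frame spatial K",
                  colour = "Retained")
}

#' Plot relative tau against relative flow with the linearity fit
#' @param object A `capillary_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.capillary_result <- function(object, ...) {
  lin <- object$linearity
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$relative_flow,
                               y = .data$relative_tau)) +
    ggplot2::geom_abline(slope = lin$slope, intercept = lin$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Q / Q[0]), y = expression(tau[0] / tau[c]),
                  title = sprintf("R^2 = %.3f", lin$r_squared))
}
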
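# autoplot() methods for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one channel of a micrograph
#'
#' @param object A [micrograph()].
#' @param channel Channel role to display.
#' @param ... Unused.
#' @return A ggplot raster of the channel.
#' @export
autoplot.micrograph <- function(object, channel = names(object$channels)[1], ...) {
  if (!channel %in% names(object$channels)) {
    stop_bad_input(sprintf("Channel '%s' not present.", channel))
  }
  m <- object$channels[[channel]]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$intensity <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "AU") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s: %s channel", object$well_id, channel),
                  x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Plot a titration fit
#'
#' @param object A `pka_fit` from [fit_pka()].
#' @param ... Unused.
#' @return A ggplot of the data with the fitted curve and the pKa midpoint.
#' @export
autoplot.pka_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$ph, y = .data$fluorescence)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pH", y = "TNS fluorescence (AU)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(ph = seq(min(object$data$ph), max(object$data$ph),
                                    length.out = 200))
    grid$fluorescence <- predict(object, grid$ph)
    p <- p +
      ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$pka, linetype = "dashed") +
      ggplot2::labs(subtitle = sprintf("apparent pKa = %.2f%s", object$pka,
                                       if (object$ionizable) "" else " (non-ionizable)"))
  }
  p
}

#' Plot a dose-response fit
#'
#' @param object A `dose_response_fit` from [fit_dose_response()].
#' @param ... Unused.
#' @return A ggplot of activity vs dose (log10 x) with the fitted curve.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  dat <- dplyr::filter(object$data, .data$concentration_uM > 0)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$concentration_uM,
                                         y = .data$activity_percent)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[Drug] (uM)", y = "metabolic activity (%)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    rng <- range(dat$concentration_uM)
    grid <- tibble::tibble(
      concentration_uM = 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200))
    grid$activity_percent <- predict(object, grid$concentration_uM)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::labs(subtitle = sprintf("%s fit", object$model))
  }
  p
}

#' Plot a mechanism regression
#'
#' @param object A `mechanism_fit` from [fit_mechanism()].
#' @param ... Unused.
#' @return A ggplot of foci per cell vs puncta per cell with the fitted
#'   line; blocker wells (zero uptake) anchor the intercept.
#' @export
autoplot.mechanism_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$puncta_per_cell,
                               y = .data$foci_per_cell)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "DiD puncta per cell (colloid uptake)",
      y = "Gal8 foci per cell",
      subtitle = sprintf("slope %.3g foci/punctum, intercept %.3g foci/cell, R^2 = %.3f",
                         object$slope, object$intercept, object$r_squared)) +
    ggplot2::theme_minimal()
}
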
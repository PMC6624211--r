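# ggplot2 presentations for each result type.

#' @importFrom ggplot2 autoplot ggplot aes
NULL

#' Plot a rho-hat estimate
#'
#' Intensity as a function of the covariate with its pointwise confidence
#' band; optionally superimposes a fitted log-linear model's
#' `exp(alpha + beta z)` curve.
#'
#' @param object A [rhohat()] result.
#' @param fit Optional [fit_loglinear_ppm()] fit to overlay.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.rho_estimate <- function(object, fit = NULL, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$z, y = .data$rho)) +
    ggplot2::geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi),
      fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(
      yintercept = attr(object, "baseline"),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = sprintf("Covariate z%s (km)", if (is.null(attr(object, "feature_class"))) {
        ""
      } else {
        paste0(": distance to ", attr(object, "feature_class"))
      }),
      y = expression(hat(rho)(z) ~ "(sightings per " * km^2 * ")")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    b <- fit$slope_beta[1]
    df$fit <- exp(fit$intercept_alpha + b * df$z)
    p <- p + ggplot2::geom_line(
      data = df, aes(y = .data$fit),
      colour = "red", linewidth = 0.7
    )
  }
  p
}

#' Plot a point-process ROC curve
#' @param object A [roc_auc()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$area_fraction, .data$point_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Fraction of study area",
      y = "Fraction of sightings captured",
      subtitle = sprintf("AUC = %.3f", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a kernel density surface
#' @param object A [kde_gaussian()] result (or any `spatial_raster`).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.spatial_raster <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = object$feature_class %||% "value") +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Plot a decomposed monthly series
#'
#' Observed, trend, seasonal and random components in stacked panels.
#'
#' @param object A [decompose_additive()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sighting_decomposition <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(t = .data$year + (.data$month - 0.5) / 12) |>
    tidyr::pivot_longer(c("observed", "trend", "seasonal", "random"),
      names_to = "component", values_to = "value"
    ) |>
    dplyr::mutate(component = factor(
      .data$component, c("observed", "trend", "seasonal", "random")
    ))
  ggplot(df, aes(.data$t, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Sightings per month") +
    ggplot2::theme_minimal()
}
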
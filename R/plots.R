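#' Plot a Hill dose-response fit
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot: data points plus the fitted curve on a log
#'   concentration axis (zero-dose points shown at the axis edge).
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  xp <- d$x[d$x > 0]
  curve_x <- exp(seq(log(min(xp)), log(max(xp)), length.out = 200))
  curve <- tibble::tibble(x = curve_x, y = predict(object, curve_x))
  ggplot2::ggplot(d[d$x > 0, ], ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand concentration", y = "signal",
                  title = sprintf("Hill fit: EC50 = %.3g, b = %.2f",
                                  object$ec50, object$b)) +
    ggplot2::theme_minimal()
}

#' Plot a Boltzmann melt fit
#'
#' @param object A `melt_fit`.
#' @param ... Unused.
#' @return A ggplot of the melt curve with the fitted sigmoid and Tm marked.
#' @export
autoplot.melt_fit <- function(object, ...) {
  d <- object$data
  curve_t <- seq(min(d$temperature), max(d$temperature), length.out = 300)
  curve <- tibble::tibble(t = curve_t, f = predict(object, curve_t))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature, y = .data$fluorescence)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$t, y = .data$f),
                       colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$tm, linetype = "dashed") +
    ggplot2::labs(x = "temperature (deg C)", y = "fluorescence",
                  title = sprintf("Boltzmann melt: Tm = %.2f deg C", object$tm)) +
    ggplot2::theme_minimal()
}

#' Plot a profile chi-square confidence contour
#'
#' @param object A `confidence_contour`.
#' @param ... Unused.
#' @return A ggplot of the chi-square ratio profile with the F-threshold
#'   line and interval bounds.
#' @export
autoplot.confidence_contour <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$value, y = .data$ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = object$parameter, y = "chisq_min / chisq",
                  title = sprintf("Confidence contour for %s", object$parameter)) +
    ggplot2::theme_minimal()
  for (b in c(object$lower, object$upper)) {
    if (!is.na(b)) p <- p + ggplot2::geom_vline(xintercept = b, colour = "grey50")
  }
  p
}

#' Plot progress curves against a kinetic fit
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot of observed product versus time, one facet-free panel
#'   with one colour per substrate level, with model curves overlaid.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  dense <- assay_design(enzyme_uM = object$design$enzyme_uM,
                        substrate_uM = object$design$substrate_uM,
                        times_min = seq(min(d$time_min) / 10, max(d$time_min),
                                        length.out = 40),
                        replicates = 1L)
  m <- model_observable(object$scheme, object$estimates[floating_rates(object$scheme)],
                        dense)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$product_uM,
                                  colour = factor(.data$substrate_uM))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = m, ggplot2::aes(y = .data$model)) +
    ggplot2::labs(x = "time (min)", y = "product (uM)",
                  colour = "substrate (uM)",
                  title = sprintf("Global fit, scheme '%s'", object$scheme$name)) +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a voxel grid channel
#'
#' @param grid A voxel array from [voxelize()].
#' @param channel Channel index or name (see [voxel_channels()]).
#' @param z_index Slice index along the z axis (default: middle).
#' @return A ggplot heat map of the slice.
#' @export
plot_voxel_slice <- function(grid, channel = "C", z_index = NULL) {
  if (is.character(channel)) channel <- match(channel, voxel_channels())
  n <- dim(grid)[1]
  if (is.null(z_index)) z_index <- ceiling(n / 2)
  df <- expand.grid(x = seq_len(n), y = seq_len(n))
  df$value <- as.vector(grid[, , z_index, channel])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("channel %s, z slice %d",
                                  voxel_channels()[channel], z_index)) +
    ggplot2::theme_minimal()
}
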
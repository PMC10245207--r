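#' Plot an isoquant fit
#'
#' Scatter of per-nest average nodule volume against nodule density with the
#' fitted constant-product curve `D = L_hat / V` overlaid.
#'
#' @param object An `isoquant_fit`.
#' @param log_scale Use log10 axes (the hyperbola becomes a straight line of
#'   slope -1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isoquant_fit
#' @export
autoplot.isoquant_fit <- function(object, log_scale = FALSE, ...) {
  d <- object$data
  vr <- range(d$volume_mm3)
  curve <- tibble::tibble(
    volume_mm3 = exp(seq(log(vr[1]), log(vr[2]), length.out = 200)),
    density_per_g = object$L_hat / exp(seq(log(vr[1]), log(vr[2]),
                                           length.out = 200))
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$volume_mm3, .data$density_per_g)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(
      x = expression("average nodule volume" ~ (mm^3)),
      y = expression("nodule density" ~ (g^-1)),
      title = sprintf("Isoquant fit: V %s D = %.2f mm³/g",
                      "×", object$L_hat)
    ) +
    ggplot2::theme_minimal()
  if (log_scale) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Plot an isoquant fit (alias)
#'
#' @inheritParams autoplot.isoquant_fit
#' @param fit An `isoquant_fit`.
#' @return A ggplot object.
#' @export
plot_isoquant <- function(fit, log_scale = FALSE) {
  autoplot(fit, log_scale = log_scale)
}

#' Nodule diameter distributions by clade
#'
#' @param nodules Per-nodule table with `clade` and `diameter_mm`.
#' @return A ggplot object: one boxplot of nodule diameters per clade,
#'   ordered by median diameter.
#' @export
plot_nodule_diameters <- function(nodules) {
  nodules <- tibble::as_tibble(nodules)
  ggplot2::ggplot(
    nodules,
    ggplot2::aes(stats::reorder(.data$clade, .data$diameter_mm,
                                FUN = stats::median),
                 .data$diameter_mm)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "Termitomyces clade", y = "nodule diameter (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic survey
#'
#' @param object A `synthetic_survey`.
#' @param ... Unused.
#' @return A ggplot object (nodule diameters by clade).
#' @method autoplot synthetic_survey
#' @export
autoplot.synthetic_survey <- function(object, ...) {
  plot_nodule_diameters(object$nodules)
}
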
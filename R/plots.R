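#' Plot methods
#'
#' ggplot2 visualisations of the pipeline stages: a screening volcano plot
#' (adjusted group difference against evidence), the MR distribution of the
#' exhaustive search by core-set size with the per-size best marked, a
#' Spearman rho heatmap, and control reference bands for a given curve.
#'
#' @param object A `gait_screen`, `coreset_search` or `gait_corr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gaitcoreset-plots
NULL

#' @rdname gaitcoreset-plots
#' @export
autoplot.gait_screen <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     z = .data$estimate / .data$std_error,
                     nlp = -log10(.data$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$nlp,
                                  colour = .data$included)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::labs(x = "adjusted group difference (t)", y = "-log10 p",
                  colour = "included",
                  title = "Step I screening: covariate-adjusted group differences") +
    ggplot2::theme_minimal()
}

#' @rdname gaitcoreset-plots
#' @export
autoplot.coreset_search <- function(object, ...) {
  d <- object$results
  best <- dplyr::slice_min(dplyr::group_by(d, .data$size), .data$mr,
                           n = 1, with_ties = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$size), y = .data$mr)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.25, size = 0.7) +
    ggplot2::geom_point(data = best, colour = "red", size = 2.5) +
    ggplot2::geom_line(data = best, ggplot2::aes(group = 1), colour = "red") +
    ggplot2::labs(x = "core-set size", y = "LOOCV misclassification rate",
                  title = "Exhaustive core-set search",
                  subtitle = "red: best MR per size") +
    ggplot2::theme_minimal()
}

#' @rdname gaitcoreset-plots
#' @export
autoplot.gait_corr <- function(object, ...) {
  vars <- attr(object, "variables")
  d <- dplyr::mutate(tibble::as_tibble(object),
                     var1 = factor(.data$var1, levels = vars),
                     var2 = factor(.data$var2, levels = rev(vars)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho",
                  title = sprintf("Spearman correlations (%s)",
                                  attr(object, "grouping"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' @rdname gaitcoreset-plots
#' @param reference A [fit_reference_bands()] object.
#' @param joint,plane,side Which curve band to draw.
#' @export
plot_reference_band <- function(reference, joint, plane, side = "affected") {
  b <- dplyr::filter(reference$bands, .data$joint == !!joint,
                     .data$plane == !!plane, .data$side == !!side)
  assert_that(nrow(b) == 101, "no band for that joint/plane/side.")
  ggplot2::ggplot(b, ggplot2::aes(x = .data$cycle_pct, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "% gait cycle", y = "angle (deg)",
                  title = sprintf("Control reference band: %s %s (%s side)",
                                  joint, plane, side)) +
    ggplot2::theme_minimal()
}
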
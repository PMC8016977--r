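#' @exportS3Method ggplot2::autoplot
autoplot.calibration <- function(object, ...) {
  ggplot2::ggplot(object$standards,
                  ggplot2::aes(x = .data$measured, y = .data$verified)) +
    ggplot2::geom_abline(slope = object$a, intercept = object$b,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression("measured " * delta^13 * "C (‰)"),
      y = expression("verified " * delta^13 * "C (‰, VPDB)"),
      title = sprintf("%s normalization: slope %.4f, intercept %.3f",
                      object$kind, object$a, object$b)
    ) +
    ggplot2::theme_minimal()
}

#' Plot \eqn{\delta^{13}}C distributions against the decision thresholds
#'
#' Histogram of tissue \eqn{\delta^{13}}C, optionally filled by pathway,
#' with the C3/C4 boundary and the CAM band drawn as reference lines — a
#' visual check that the classified groups separate cleanly.
#'
#' @param deltas Tibble with a `delta13C` column and optionally `pathway`.
#' @param rules A [classification_rules()].
#' @param binwidth Histogram bin width (permil).
#' @return A ggplot object.
#' @export
plot_delta_distribution <- function(deltas, rules = classification_rules(),
                                    binwidth = 0.5) {
  stopifnot(is.data.frame(deltas), "delta13C" %in% names(deltas))
  aes <- if ("pathway" %in% names(deltas)) {
    ggplot2::aes(x = .data$delta13C, fill = .data$pathway)
  } else {
    ggplot2::aes(x = .data$delta13C)
  }
  ggplot2::ggplot(deltas, aes) +
    ggplot2::geom_histogram(binwidth = binwidth, colour = "grey30",
                            linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = rules$c3_c4_threshold,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(rules$cam_lower, rules$cam_upper),
                        linetype = "dotted") +
    ggplot2::labs(x = expression(delta^13 * "C (‰, VPDB)"),
                  y = "specimens") +
    ggplot2::theme_minimal()
}

#' Plot per-plot pathway cover
#'
#' Stacked bars of cover by pathway per plot, the standard way to eyeball
#' the C3/C4 balance across a plot network.
#'
#' @param pw_cover Output of [pathway_cover()].
#' @return A ggplot object.
#' @export
plot_pathway_cover <- function(pw_cover) {
  stopifnot(is.data.frame(pw_cover),
            all(c("plot_id", "pathway", "cover_pct") %in% names(pw_cover)))
  ggplot2::ggplot(pw_cover,
                  ggplot2::aes(x = .data$plot_id, y = .data$cover_pct,
                               fill = .data$pathway)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "cover (%)", fill = "pathway") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
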
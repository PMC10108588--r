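#' Plot a randomization test result
#'
#' Statistic trace over time with the per-timepoint p-values and the
#' segments surviving the run-length rule shaded.
#'
#' @param object A `randomization_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.randomization_result <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms))
  if (nrow(object$segments)) {
    p <- p + ggplot2::geom_rect(
      data = object$segments,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.6)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$statistic)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time (ms)",
                  y = if (object$method == "tanova") "DISS" else "GFP of average",
                  title = sprintf("%s (%d iterations, alpha = %g)",
                                  toupper(object$method), object$n_iter,
                                  object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot microstate activations over time
#'
#' One activation time-course per template (the share of the average map's
#' variance each template explains), with significant-activation periods
#' marked, over the group-average GFP.
#'
#' @param object An `activation_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activation_series <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms,
                                       y = .data$activation,
                                       colour = .data$template_id))
  if (!is.null(object$active)) {
    act <- d[!is.na(d$active) & d$active, ]
    if (nrow(act)) {
      p <- p + ggplot2::geom_point(data = act, size = 0.4)
    }
  }
  p +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time (ms)", y = "Explained variance fraction",
                  colour = "Microstate") +
    ggplot2::theme_minimal()
}

#' Plot microstate template loadings
#'
#' Channel loadings of every template as a heat strip; a quick visual check
#' of template distinctness (full topographic rendering is left to
#' dedicated EEG toolboxes).
#'
#' @param object A `microstate_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.microstate_set <- function(object, ...) {
  d <- tidy(object)
  d$channel <- factor(d$channel, levels = object$montage)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$channel, y = .data$template_id,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Loading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the distribution of NFCS totals
#'
#' Dot histogram of per-subject constellation totals (optionally per
#' group), the standard way these strongly bimodal score distributions are
#' shown, with the clinical threshold marked.
#'
#' @param scores Tibble with a `total` column (e.g. from [score_nfcs()]),
#'   optionally `group`.
#' @param threshold Clinical threshold to mark (default 9).
#' @param binwidth Dot bin width (default 1 score point).
#' @return A ggplot object.
#' @export
plot_nfcs_distribution <- function(scores, threshold = 9, binwidth = 1) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$total)) +
    ggplot2::geom_dotplot(binwidth = binwidth, method = "histodot") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Constellation total", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if ("group" %in% names(scores)) {
    p <- p + ggplot2::facet_wrap(~group, ncol = 1)
  }
  p
}
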
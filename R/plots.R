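#' Plot the distribution of cross-validation accuracies
#'
#' Histogram of the per-fold accuracies with the overall mean marked.
#'
#' @param object A `"wcmfe_cv"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wcmfe_cv
#' @export
autoplot.wcmfe_cv <- function(object, ...) {
  acc <- tidy(object)
  m <- mean(acc$accuracy)
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(binwidth = 2.5, boundary = 0,
                            fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = m, linetype = 2) +
    ggplot2::labs(x = "fold accuracy (%)", y = "count",
                  title = sprintf("%d x %d-fold CV, mean %.2f%%",
                                  object$repeats, object$k, m)) +
    ggplot2::theme_minimal()
}

#' Plot class-mean entropy curves
#'
#' Lines per class label from the output of [mean_entropy_curve()], with an
#' optional shaded interval (e.g. the selected analysis window).
#'
#' @param curves Output of [mean_entropy_curve()].
#' @param interval Optional `c(b, d)` to shade.
#' @return A ggplot object.
#' @export
plot_entropy_curves <- function(curves, interval = NULL) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$start, y = .data$value,
                                            colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window start (sample)", y = "mean entropy",
                  colour = "class") +
    ggplot2::theme_minimal()
  if (!is.null(interval)) {
    p <- p + ggplot2::annotate("rect", xmin = interval[1], xmax = interval[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.1)
  }
  p
}

#' Plot the frequency response of weight-factor filters
#'
#' Magnitude responses of one or more coarse-graining weight vectors over
#' normalised frequency, showing their low-pass character.
#'
#' @param weights A single weight vector or a named list of them.
#' @param n_freqs Grid points over `[0, pi]`.
#' @return A ggplot object.
#' @export
plot_filter_response <- function(weights, n_freqs = 512) {
  if (!is.list(weights)) weights <- list(weights = weights)
  if (is.null(names(weights)) || any(names(weights) == "")) {
    names(weights) <- paste0("w", seq_along(weights))
  }
  resp <- purrr::imap_dfr(weights, function(w, nm) {
    dplyr::mutate(filter_frequency_response(w, n_freqs), filter = nm)
  })
  ggplot2::ggplot(resp, ggplot2::aes(x = .data$frequency,
                                     y = .data$magnitude,
                                     colour = .data$filter)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(omega / pi), y = "|H|") +
    ggplot2::theme_minimal()
}
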
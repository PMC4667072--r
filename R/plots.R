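#' Plot a length distribution of classified species
#'
#' Read-weighted length histogram (the HMW length-distribution plot), one
#' panel colour per source guide.
#'
#' @param histogram Tibble from [length_histogram()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$length, y = .data$reads,
                               fill = .data$guide)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "insert length (nt)", y = "reads",
                  fill = "source guide") +
    ggplot2::theme_minimal()
}

#' Plot the class composition of a classified library
#'
#' @param classified Tibble from [classify_inserts()]; `count` weights by
#'   reads when present.
#' @return A ggplot object.
#' @export
plot_class_composition <- function(classified) {
  if (!"count" %in% names(classified)) classified$count <- 1L
  df <- classified |>
    dplyr::count(.data$class, wt = .data$count, name = "reads") |>
    dplyr::mutate(class = factor(.data$class, levels = species_classes()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$reads)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot HMW composition (pie-chart analogue)
#'
#' Concatemer / 5'-tailing / 3'-tailing proportions within the fold-change
#' window, per library.
#'
#' @param x An `hmw_fc` object from [hmw_fold_change()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hmw_fc <- function(x, ...) {
  ggplot2::ggplot(x$composition,
                  ggplot2::aes(x = .data$library, y = .data$proportion,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "proportion of HMW reads",
                  fill = NULL,
                  title = sprintf("HMW composition (%d-%d nt)",
                                  x$window[1], x$window[2])) +
    ggplot2::theme_minimal()
}

#' Plot observed vs division-corrected decay
#'
#' @param x A `decay_fit` from [division_normalized_decay()].
#' @param ... Unused.
#' @return A ggplot object (log2 signal scale).
#' @exportS3Method ggplot2::autoplot
autoplot.decay_fit <- function(x, ...) {
  df <- x$series |>
    tidyr::pivot_longer(c("signal", "corrected"), names_to = "series",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = "time (h)", y = "signal (AU)",
                  subtitle = sprintf("t_obs = %.1f h, Td = %.0f h, k = %.4f /h%s",
                                     x$t_obs, x$doubling_time, x$k_decay,
                                     if (x$no_active_decay)
                                       " (no active decay)" else "")) +
    ggplot2::theme_minimal()
}
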
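## ggplot2 views of the main result types.

#' Plot the strand-collapsed substitution spectrum
#'
#' @param records Mutation records (or class counts with `n`).
#' @return A ggplot.
#' @export
plot_spectrum <- function(records) {
  records <- as_tibble(records)
  counts <- if ("n" %in% names(records)) {
    records
  } else {
    records |> filter(!is.na(.data$substitution_class)) |>
      count(.data$substitution_class)
  }
  counts <- counts |>
    mutate(substitution_class = factor(.data$substitution_class,
                                       levels = SUBSTITUTION_CLASSES),
           transition = .data$substitution_class %in% TRANSITION_CLASSES)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$substitution_class,
                                       y = .data$n, fill = .data$transition)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
                               labels = c(`TRUE` = "transition", `FALSE` = "transversion"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "substitutions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot indel size distribution
#'
#' @param records Mutation records with `indel_size`.
#' @param max_size Largest |size| shown.
#' @return A ggplot.
#' @export
plot_indel_sizes <- function(records, max_size = 10L) {
  d <- as_tibble(records) |>
    filter(!is.na(.data$indel_size), abs(.data$indel_size) <= max_size) |>
    mutate(type = if_else(.data$indel_size < 0, "deletion", "insertion"),
           size = abs(.data$indel_size)) |>
    count(.data$type, .data$size)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$n, fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = seq_len(max_size)) +
    ggplot2::labs(x = "indel size (bp)", y = "events", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot homopolymer-length-resolved indel rates
#'
#' @param hp_rates Output of [homopolymer_indel_rates()].
#' @return A ggplot.
#' @export
plot_homopolymer_rates <- function(hp_rates) {
  ggplot2::ggplot(hp_rates,
                  ggplot2::aes(x = .data$run_length, y = .data$rate,
                               colour = .data$base_class,
                               linetype = if ("direction" %in% names(hp_rates))
                                 .data$direction else NULL)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "homopolymer run length (bp)",
                  y = "events / run / generation",
                  colour = "base class", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname bin_rates
#' @param object A `mutability_bins` object.
#' @param ... Unused.
#' @export
autoplot.mutability_bins <- function(object, ...) {
  d <- object$bins |> filter(.data$B > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$rate)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$B), alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#2166ac") +
    ggplot2::labs(x = "predicted mutability (bin midpoint)",
                  y = "mutation rate / site / generation",
                  size = "sites in bin") +
    ggplot2::theme_minimal()
}

#' @rdname fit_penalized_logistic
#' @param object A `mutability_model`.
#' @param top_n Predictors shown.
#' @param ... Unused.
#' @export
autoplot.mutability_model <- function(object, top_n = 15L, ...) {
  d <- odds_ratios(object) |> head(top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio,
                                  y = stats::reorder(.data$predictor,
                                                     abs(.data$coefficient)))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
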
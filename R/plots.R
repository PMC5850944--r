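#' @export
autoplot.bn_k_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("k", "n_couples", "n_redundant")],
                              -"k", names_to = "quantity",
                              values_to = "count")
  long$quantity <- dplyr::recode(long$quantity,
                                 n_couples = "non-redundant couples",
                                 n_redundant = "redundant couples")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$count,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "selected proteins (k)", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the selection sweep over k
#' @param sweep a tibble from [sweep_k()].
#' @param ... passed on to [autoplot.bn_k_sweep()].
#' @return a ggplot object.
#' @export
plot_k_sweep <- function(sweep, ...) autoplot.bn_k_sweep(sweep, ...)

#' @export
autoplot.bn_family <- function(object, ...) {
  freq <- clause_frequencies(object)
  freq$label <- factor(freq$label, levels = rev(freq$label))
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$frequency, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "frequency across the family", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot clause frequencies of a learned family
#' @param family a `bn_family`.
#' @param ... passed on to [autoplot.bn_family()].
#' @return a ggplot object.
#' @export
plot_clause_frequencies <- function(family, ...) autoplot.bn_family(family, ...)

#' @export
autoplot.bn_predictions <- function(object, ...) {
  cls <- object[object$label %in% c("CR", "PR", "unknown"), ]
  ggplot2::ggplot(cls, ggplot2::aes(x = .data$truth, y = .data$confidence)) +
    ggplot2::geom_jitter(width = 0.15, height = 0,
                         ggplot2::aes(colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "true class", y = "confidence (1 = CR)",
                  colour = "predicted") +
    ggplot2::theme_minimal()
}

#' Plot per-patient classification confidence by true class
#' @param predictions a tibble from [classify_patients()].
#' @param ... passed on to [autoplot.bn_predictions()].
#' @return a ggplot object.
#' @export
plot_confidence <- function(predictions, ...) {
  autoplot.bn_predictions(predictions, ...)
}
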
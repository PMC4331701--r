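#' Plot the trimmed insert-length distribution
#'
#' Bar plot of the fraction of trimmed pairs cut at each insert length;
#' under the default benchmark (Gaussian adapter length, mean 20, reads of
#' 101) the mode sits near 81 bases.
#'
#' @param ld A tibble from [length_distribution()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(ld) {
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$insert_length,
                                   y = .data$fraction)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = "trimmed insert length (bases)",
                  y = "fraction of trimmed pairs") +
    ggplot2::theme_minimal()
}

#' Plot a quality model's per-position profile
#'
#' Mean Phred score by read position with a one-SD ribbon, showing the
#' 3'-ward decline the simulator's error model follows.
#'
#' @param object A `quality_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quality_model <- function(object, ...) {
  q <- object$q_values
  mu <- as.vector(object$probs %*% q)
  ex2 <- as.vector(object$probs %*% q^2)
  s <- sqrt(pmax(ex2 - mu^2, 0))
  df <- tibble(position = seq_len(object$read_length), mean_q = mu, sd_q = s)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean_q)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_q - .data$sd_q,
                                      ymax = .data$mean_q + .data$sd_q),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "read position", y = "Phred quality") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
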
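#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a candidate table
#'
#' Lollipop chart of composite hazard scores for the ranked candidates,
#' highest priority at the top.
#'
#' @param object A `fampri_candidates` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fampri_candidates <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No candidate variants retained"))
  }
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hazard_score, y = .data$gene)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$hazard_score,
                                       yend = .data$gene),
                          linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_point(size = 3, colour = "#2c7fb8") +
    ggplot2::scale_x_continuous(limits = c(0, 3),
                                breaks = seq(0, 3, 0.5)) +
    ggplot2::labs(x = "composite hazard score", y = NULL,
                  title = "Ranked candidate variants") +
    ggplot2::theme_minimal()
}

#' Plot the cascade audit funnel
#'
#' Bar chart of the number of variants surviving each cascade stage.
#'
#' @param candidates A `fampri_candidates` table.
#' @return A ggplot object.
#' @export
plot_stage_counts <- function(candidates) {
  sc <- stage_counts(candidates)
  sc$stage <- factor(sc$stage, levels = sc$stage)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "variants surviving",
                  title = "Filter cascade audit") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
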
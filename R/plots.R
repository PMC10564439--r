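#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ranked gene list
#'
#' Bar chart of final scores for the top-ranked genes.
#'
#' @param object a `ranked_genes` tibble.
#' @param top_n how many leading genes to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_genes <- function(object, top_n = 20L, ...) {
  dat <- utils::head(tibble::as_tibble(object), top_n)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$symbol, -.data$final_score),
    y = .data$final_score)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "final score",
                  title = attr(object, "disease") %||% "gene ranking") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a permutation path test
#'
#' Box plot of the null shortest-path statistics with the observed value as
#' a horizontal line — the query-vs-random contrast.
#'
#' @param object a `path_test` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.path_test <- function(object, ...) {
  null <- tibble(statistic = object$null[is.finite(object$null)])
  ggplot2::ggplot(null, ggplot2::aes(x = "random", y = .data$statistic)) +
    ggplot2::geom_boxplot(width = 0.3, fill = "grey85") +
    ggplot2::geom_hline(yintercept = object$observed,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::annotate("text", x = 1.35, y = object$observed,
                      label = sprintf("observed (p = %.3g)", object$p_value),
                      hjust = 0, vjust = -0.5, size = 3) +
    ggplot2::labs(x = NULL, y = "mean shortest-path length") +
    ggplot2::theme_minimal()
}

#' Plot top-k validation statistics
#'
#' ELFC and HGPV against the cutoff k.
#'
#' @param object a `topk_validation` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.topk_validation <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("elfc", "hgpv"),
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ statistic, scales = "free_y") +
    ggplot2::labs(x = "top-k cutoff", y = NULL) +
    ggplot2::theme_minimal()
}
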
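#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score curves along the recovered series
#'
#' Bayes- and mean-score trajectories against the linearized rank, faceted
#' by score family.
#'
#' @param object a [score_track()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.score_track <- function(object, ...) {
  tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(score_columns), names_to = "score",
                        values_to = "value") |>
    dplyr::mutate(family = ifelse(grepl("^bayes", .data$score),
                                  "Bayes-scores", "mean-scores")) |>
    ggplot2::ggplot(ggplot2::aes(.data$rank, .data$value,
                                 colour = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~family, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "position along recovered cycle", y = "score") +
    ggplot2::theme_minimal()
}

#' Circular positions of a consensus order
#'
#' @param object a `consensus_order`.
#' @param truth optional numeric vector of true phases (same cell order) for
#'   a recovered-vs-true comparison.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.consensus_order <- function(object, truth = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(truth)) {
    df$truth <- truth
    ggplot2::ggplot(df, ggplot2::aes(.data$truth, .data$theta)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = "true phase", y = "recovered position") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$linear_rank, .data$theta)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = "linear rank", y = "circular position") +
      ggplot2::theme_minimal()
  }
}

#' Stage segmentation along the series
#'
#' @param object a `stage_path`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stage_path <- function(object, ...) {
  tibble::as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$rank, 1, fill = .data$stage)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position along recovered cycle", y = NULL,
                  fill = "stage") +
    ggplot2::theme_minimal()
}

#' Methylation track along the series
#'
#' @param object a `methylation_track`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.methylation_track <- function(object, ...) {
  tibble::as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$rank)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$level), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "red") +
    ggplot2::labs(x = "position along recovered cycle",
                  y = "methylation level") +
    ggplot2::theme_minimal()
}

#' Smoothed expression of selected genes along the series
#'
#' @param mat log2-layer [expr_matrix()].
#' @param order a `consensus_order`.
#' @param genes gene ids to draw.
#' @return a ggplot of observed points and RTS-smoothed curves.
#' @export
plot_smoothed_genes <- function(mat, order, genes) {
  ids <- order$cell_id[order(order$linear_rank)]
  df <- purrr::map(genes, function(g) {
    e <- mat$values[g, ids]
    rts_smooth(fit_rwp(e), e, gene_id = g)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(.data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), alpha = 0.3,
                        size = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "red") +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "position along recovered cycle",
                  y = "log2 expression") +
    ggplot2::theme_minimal()
}
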
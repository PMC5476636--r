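#' Correlation-score of a recovered cycle
#'
#' Agreement between a circular order and experimentally determined stage
#' labels: the cycle of k clusters is cut at each of its k edges and
#' traversed in both directions, each cell receives the sequential index of
#' its cluster along the linear path, and the maximum Pearson correlation
#' between those indices and the labels over all 2k linearizations is
#' returned.
#'
#' For a cell-level order (a `consensus_order`), every cell is its own
#' cluster (`k = n`) and the cuts run over all cell boundaries.
#'
#' @param cycle either a `consensus_order` tibble, or a list with
#'   `node_order` (a `tour_cycle`) plus `assignment` (per-cell cluster
#'   labels in the same id universe as `labels`), or directly an integer
#'   vector of per-cell cluster indices along the cycle (1..k in tour
#'   order).
#' @param labels integer stage labels (e.g. 1 = G0/G1, 2 = S, 3 = G2/M),
#'   non-constant; extra stages may be merged by renumbering beforehand.
#' @param k number of clusters of the cycle (defaults to `max(cycle)` for a
#'   vector input).
#' @return maximum Pearson correlation in `[-1, 1]`.
#' @export
correlation_score <- function(cycle, labels, k = NULL) {
  if (inherits(cycle, "consensus_order") ||
      (is.data.frame(cycle) && all(c("cell_id", "linear_rank") %in% names(cycle)))) {
    idx <- cycle$linear_rank
    k <- nrow(cycle)
  } else if (is.list(cycle) && !is.null(cycle$node_order)) {
    pos <- match(cycle$assignment, cycle$node_order)
    idx <- pos
    if (is.null(k)) k <- length(cycle$node_order)
  } else {
    idx <- as.integer(cycle)
    if (is.null(k)) k <- max(idx)
  }
  labels <- as.numeric(labels)
  n <- length(labels)
  stopifnot(length(idx) == n, n >= 3)
  if (stats::var(labels) == 0) {
    stop("correlation-score undefined: constant labels", call. = FALSE)
  }
  best <- -Inf
  for (cut in seq_len(k)) {
    l <- ((idx - cut) %% k) + 1          # path starting at cluster `cut`
    best <- max(best, stats::cor(labels, l), stats::cor(labels, k + 1 - l))
  }
  best
}

#' Change-index of a linearized series
#'
#' Counts the label changes `s_c` between adjacent cells along a linearized
#' series and returns `1 - (s_c - 2)/(N - 3)`: a perfect series changes
#' labels exactly twice (G1 to S and S to G2/M) and scores 1, while the
#' worst series (`s_c = N - 1`) scores 0. Fewer than two changes (degenerate
#' label sets) would exceed 1; such values are clamped to 1 with a warning.
#'
#' @param labels experimentally determined labels along the linearized
#'   series (length `N >= 4`, at least 2 distinct values).
#' @return change-index in `[0, 1]`.
#' @export
change_index <- function(labels) {
  N <- length(labels)
  if (N < 4) stop("change-index needs N >= 4", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("change-index needs at least 2 label classes", call. = FALSE)
  }
  s_c <- sum(labels[-1] != labels[-N])
  val <- 1 - (s_c - 2) / (N - 3)
  if (s_c < 2) {
    warning("fewer than 2 label changes; change-index clamped to 1",
            call. = FALSE)
    val <- 1
  }
  val
}

#' Read a per-cell stage label table
#'
#' Two-column TSV `(cell_id, stage)`; stages are returned as given (map to
#' integers with `label_numbers` when scoring).
#'
#' @param path TSV path.
#' @return tibble `cell_id`, `stage`.
#' @export
read_stage_labels <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1:2] <- c("cell_id", "stage")
  tibble::as_tibble(df)
}

#' Map stage names to evaluation label numbers
#'
#' Default mapping merges G0 into G0/G1 = 1, S = 2, G2/M = 3 (the label
#' numbering the scoring metrics assume); supply `mapping` to override.
#'
#' @param stage character stage names.
#' @param mapping named integer vector.
#' @return integer labels.
#' @export
label_numbers <- function(stage,
                          mapping = c(G0 = 1L, G1 = 1L, S = 2L, G2M = 3L,
                                      `G2/M` = 3L)) {
  out <- mapping[as.character(stage)]
  if (any(is.na(out))) {
    stop("no label number for stage(s): ",
         paste(unique(stage[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}
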
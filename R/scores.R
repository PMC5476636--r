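#' Train a marker gene-pair stage classifier
#'
#' Supervised Naive Bayes over binary gene-pair comparisons: for every
#' ordered gene pair (a, b) and stage, the concordance frequency is the
#' fraction of that stage's cells with `e_a >= e_b` (equality counts as the
#' "1" outcome, deterministically). Pairs are ranked per stage by the margin
#' between their own-stage frequency and the best other-stage frequency; the
#' top `pairs_per_stage` per stage are unified into one pair set of size
#' `N_p`, and per-stage Bernoulli probabilities are Laplace (+1/+2)
#' smoothed.
#'
#' @param mat log2-layer [expr_matrix()].
#' @param labels per-cell stage labels in `{"G1","S","G2M"}` (named by cell
#'   id or aligned with the matrix columns).
#' @param pairs_per_stage informative pairs kept per stage (default 100).
#' @return object of class `gene_pair_model`: `pairs` (tibble gene_a,
#'   gene_b), `probs` (N_p x 3 matrix of smoothed concordance
#'   probabilities), `priors` (uniform 1/3), `n_pairs`.
#' @export
train_gene_pairs <- function(mat, labels, pairs_per_stage = 100L) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "log2") stop("training expects the log2 layer", call. = FALSE)
  stages <- c("G1", "S", "G2M")
  labels <- align_labels(labels, cell_ids(mat))
  if (!all(labels %in% stages)) {
    stop("labels must be in {G1, S, G2M}", call. = FALSE)
  }
  tab <- table(factor(labels, levels = stages))
  if (any(tab < 2)) stop("need at least 2 cells per stage", call. = FALSE)
  V <- mat$values                       # genes x cells
  m <- nrow(V)
  # per-stage concordance frequency matrices F[a, b] = mean(e_a >= e_b)
  freq <- lapply(stages, function(s) {
    cols <- which(labels == s)
    acc <- matrix(0, m, m)
    for (c_ in cols) acc <- acc + outer(V[, c_], V[, c_], ">=")
    acc / length(cols)
  })
  names(freq) <- stages
  keep <- matrix(TRUE, m, m); diag(keep) <- FALSE
  sel <- list()
  for (s in stages) {
    other <- do.call(pmax, freq[setdiff(stages, s)])
    margin <- freq[[s]] - other
    margin[!keep] <- -Inf
    ord <- order(margin, decreasing = TRUE)
    pos <- ord[margin[ord] > 0]
    if (length(pos) < pairs_per_stage) {
      warning("stage ", s, ": only ", length(pos),
              " informative pairs (requested ", pairs_per_stage, ")",
              call. = FALSE)
    }
    sel[[s]] <- utils::head(pos, pairs_per_stage)
  }
  idx <- sort(unique(unlist(sel)))
  ab <- arrayInd(idx, c(m, m))
  genes <- rownames(V)
  probs <- vapply(stages, function(s) {
    cols <- which(labels == s)
    ones <- vapply(seq_len(nrow(ab)), function(i) {
      sum(V[ab[i, 1], cols] >= V[ab[i, 2], cols])
    }, numeric(1))
    (ones + 1) / (length(cols) + 2)
  }, numeric(nrow(ab)))
  model <- list(
    pairs = tibble::tibble(gene_a = genes[ab[, 1]], gene_b = genes[ab[, 2]]),
    probs = probs, priors = stats::setNames(rep(1 / 3, 3), stages),
    n_pairs = nrow(ab), stages = stages)
  class(model) <- "gene_pair_model"
  model
}

align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss)) stop("labels missing for cells: ",
                           paste(utils::head(miss, 3), collapse = ", "),
                           call. = FALSE)
    labels <- labels[ids]
  }
  if (length(labels) != length(ids)) {
    stop("label vector length does not match the number of cells", call. = FALSE)
  }
  as.character(labels)
}

#' @export
print.gene_pair_model <- function(x, ...) {
  cat(sprintf("<gene_pair_model> %d unified gene pairs over stages %s\n",
              x$n_pairs, paste(x$stages, collapse = "/")))
  invisible(x)
}

#' Stage log-posterior (Bayes) scores
#'
#' For an expression vector, binarize each model pair to `x_i = 1` when
#' `e_a >= e_b` (else 0) and return, per stage, the log10 of the Bernoulli
#' product times the uniform prior:
#' `log10 P(sigma) + sum_i x_i log10 p_i + (1 - x_i) log10(1 - p_i)`.
#'
#' @param model a [train_gene_pairs()] model.
#' @param expr named expression vector (log2 layer) covering all pair genes.
#' @return named numeric of length 3 (G1, S, G2M), each `<= log10(1/3)`.
#' @export
bayes_scores <- function(model, expr) {
  need <- unique(c(model$pairs$gene_a, model$pairs$gene_b))
  miss <- setdiff(need, names(expr))
  if (length(miss)) stop("expression vector lacks gene(s): ",
                         paste(utils::head(miss, 3), collapse = ", "),
                         call. = FALSE)
  x <- as.numeric(expr[model$pairs$gene_a] >= expr[model$pairs$gene_b])
  sc <- colSums(x * log10(model$probs) + (1 - x) * log10(1 - model$probs)) +
    log10(model$priors)
  stats::setNames(sc, model$stages)
}

#' Restrict a gene-pair model to available genes
#'
#' Drops pairs with either gene absent from `genes` (useful when applying a
#' model trained on another platform or gene universe); warns with the
#' count dropped and errors when nothing remains.
#'
#' @param model a `gene_pair_model`.
#' @param genes character vector of available gene ids.
#' @return a `gene_pair_model` over the surviving pairs.
#' @export
subset_pair_model <- function(model, genes) {
  keep <- model$pairs$gene_a %in% genes & model$pairs$gene_b %in% genes
  if (!any(keep)) stop("no model gene pair is covered by the supplied genes",
                       call. = FALSE)
  if (!all(keep)) {
    warning(sum(!keep), " of ", length(keep),
            " gene pairs dropped (genes absent)", call. = FALSE)
  }
  model$pairs <- model$pairs[keep, , drop = FALSE]
  model$probs <- model$probs[keep, , drop = FALSE]
  model$n_pairs <- sum(keep)
  model
}

#' Build the six stage marker sets from a catalog
#'
#' One gene set per annotated peak stage (G1, G1/S, S, G2, G2/M, M), ordered
#' by catalog rank and optionally truncated to the `top_n` best-ranked genes
#' per stage.
#'
#' @param catalog a [gene_catalog()].
#' @param top_n optional per-stage truncation by rank.
#' @return named list of six character vectors (class `mean_score_sets`).
#' @export
mean_score_sets <- function(catalog, top_n = Inf) {
  sets <- catalog |>
    dplyr::arrange(.data$rank) |>
    dplyr::group_by(.data$peak_stage)
  if (is.finite(top_n)) sets <- dplyr::slice_head(sets, n = top_n)
  sets <- dplyr::summarise(sets, genes = list(.data$gene_id), .groups = "drop")
  out <- stats::setNames(sets$genes, as.character(sets$peak_stage))
  stages <- c("G1", "G1/S", "S", "G2", "G2/M", "M")
  if (!all(stages %in% names(out))) {
    stop("catalog lacks genes for stage(s): ",
         paste(setdiff(stages, names(out)), collapse = ", "), call. = FALSE)
  }
  structure(out[stages], class = "mean_score_sets")
}

#' Stage mean-scores
#'
#' Unsupervised stage evidence: for each of the six peak-stage marker sets,
#' the arithmetic mean of the member genes' log2 expression. Genes absent
#' from the vector are skipped with a warning; a set with no present gene is
#' an error.
#'
#' @param expr named log2 expression vector.
#' @param sets a [mean_score_sets()] list.
#' @return named numeric of length 6.
#' @export
mean_scores <- function(expr, sets) {
  out <- vapply(names(sets), function(s) {
    g <- sets[[s]]
    present <- g[g %in% names(expr)]
    if (!length(present)) stop("no genes of stage set ", s,
                               " present in the expression vector", call. = FALSE)
    if (length(present) < length(g)) {
      warning(length(g) - length(present), " gene(s) of stage set ", s,
              " absent; skipped", call. = FALSE)
    }
    mean(expr[present])
  }, numeric(1))
  stats::setNames(out, names(sets))
}

#' Nine-dimensional score track along an order
#'
#' Per ordered unit, the three Bayes-scores followed by the six mean-scores —
#' the observation vector the stage HMM segments. At `granularity =
#' "cluster"` the scores are computed on cluster-mean expression and every
#' member cell inherits its cluster's scores.
#'
#' @param order a `consensus_order` (or any tibble with `cell_id`,
#'   `linear_rank`).
#' @param mat log2-layer [expr_matrix()] covering the order's cells.
#' @param model a [train_gene_pairs()] model.
#' @param sets a [mean_score_sets()] list.
#' @param granularity `"cell"` or `"cluster"`.
#' @param clusters per-cell cluster labels (required for `"cluster"`).
#' @return a `score_track` tibble: `cell_id`, `rank`, `bayes_G1`, `bayes_S`,
#'   `bayes_G2M`, `mean_G1`, `mean_G1S`, `mean_S`, `mean_G2`, `mean_G2M`,
#'   `mean_M`.
#' @export
score_track <- function(order, mat, model, sets,
                        granularity = c("cell", "cluster"), clusters = NULL) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(mat, "expr_matrix"))
  ids <- order$cell_id[order(order$linear_rank)]
  miss <- setdiff(ids, cell_ids(mat))
  if (length(miss)) stop("order refers to cells absent from the matrix: ",
                         paste(utils::head(miss, 3), collapse = ", "),
                         call. = FALSE)
  V <- mat$values[, ids, drop = FALSE]
  if (granularity == "cluster") {
    if (is.null(clusters)) stop("cluster granularity needs `clusters`",
                                call. = FALSE)
    clusters <- align_labels(clusters, ids)
    prof <- vapply(split(seq_along(ids), clusters),
                   function(j) rowMeans(V[, j, drop = FALSE]),
                   numeric(nrow(V)))
    score_one <- function(i) {
      e <- prof[, clusters[i]]
      names(e) <- rownames(V)
      c(bayes_scores(model, e), mean_scores(e, sets))
    }
  } else {
    score_one <- function(i) {
      e <- V[, i]
      names(e) <- rownames(V)
      c(bayes_scores(model, e), mean_scores(e, sets))
    }
  }
  S <- t(vapply(seq_along(ids), score_one, numeric(9)))
  colnames(S) <- c("bayes_G1", "bayes_S", "bayes_G2M",
                   "mean_G1", "mean_G1S", "mean_S", "mean_G2", "mean_G2M",
                   "mean_M")
  out <- dplyr::bind_cols(tibble::tibble(cell_id = ids, rank = seq_along(ids)),
                          tibble::as_tibble(S))
  class(out) <- c("score_track", class(out))
  out
}

score_columns <- c("bayes_G1", "bayes_S", "bayes_G2M", "mean_G1", "mean_G1S",
                   "mean_S", "mean_G2", "mean_G2M", "mean_M")

#' Serialize / load a gene-pair model as JSON
#' @param model a `gene_pair_model`.
#' @param path JSON path.
#' @export
write_gene_pair_model <- function(model, path) {
  jsonlite::write_json(
    list(version = "1", stages = model$stages,
         gene_a = model$pairs$gene_a, gene_b = model$pairs$gene_b,
         probs = model$probs, priors = model$priors),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_gene_pair_model
#' @export
read_gene_pair_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  probs <- matrix(j$probs, ncol = 3, byrow = FALSE)
  if (!is.null(dim(j$probs))) probs <- j$probs
  colnames(probs) <- j$stages
  model <- list(pairs = tibble::tibble(gene_a = j$gene_a, gene_b = j$gene_b),
                probs = probs,
                priors = stats::setNames(unlist(j$priors), j$stages),
                n_pairs = length(j$gene_a), stages = j$stages)
  class(model) <- "gene_pair_model"
  model
}
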
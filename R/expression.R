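#' Expression matrix container
#'
#' A light S3 record around a genes x cells numeric matrix with a unit tag
#' (`counts`, `TPM`, `FPKM`) and a layer tag recording provenance
#' (`raw` -> `normalized` -> `log2`). Gene and cell identifiers live in the
#' dimnames and must be unique.
#'
#' @param values numeric genes x cells matrix with unique rownames (genes)
#'   and colnames (cells); no negative entries.
#' @param unit one of `"counts"`, `"TPM"`, `"FPKM"`.
#' @param layer one of `"raw"`, `"normalized"`, `"log2"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, unit = c("TPM", "FPKM", "counts"),
                        layer = c("raw", "normalized", "log2")) {
  unit <- match.arg(unit)
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ",
         paste(utils::head(unique(rownames(values)[duplicated(rownames(values))]), 3),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate cell ids: ",
         paste(utils::head(unique(colnames(values)[duplicated(colnames(values))]), 3),
               collapse = ", "), call. = FALSE)
  }
  if (any(values < 0)) stop("negative expression values are not allowed", call. = FALSE)
  structure(list(values = values, unit = unit, layer = layer),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells  unit=%s  layer=%s\n",
              nrow(x$values), ncol(x$values), x$unit, x$layer))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and cell identifiers
#' @param mat an [expr_matrix()].
#' @return character vector of ids.
#' @export
gene_ids <- function(mat) rownames(mat$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(mat) colnames(mat$values)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long-form view of an expression matrix
#'
#' @param x an [expr_matrix()].
#' @param ... unused.
#' @return a tibble with columns `gene_id`, `cell_id`, `expression`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell_id", values_to = "expression")
}

#' Read an expression matrix from disk
#'
#' Dense TSV/CSV (first column gene ids, header row cell ids) or MatrixMarket
#' coordinate format with `genes.txt` / `cells.txt` sidecars in the same
#' directory. Orientation on disk is genes x cells; use `transpose = TRUE`
#' for cells x genes dialects.
#'
#' @param path file path (for `"mtx"`, the `.mtx` file).
#' @param format `"tsv"`, `"csv"`, or `"mtx"`.
#' @param unit expression unit tag.
#' @param transpose set `TRUE` when the file stores cells x genes.
#' @return an [expr_matrix()] with `layer = "raw"`.
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx"),
                            unit = c("TPM", "FPKM", "counts"),
                            transpose = FALSE) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    dir <- dirname(path)
    gf <- file.path(dir, "genes.txt")
    cf <- file.path(dir, "cells.txt")
    if (!file.exists(gf) || !file.exists(cf)) {
      stop("mtx input needs genes.txt and cells.txt sidecars in ", dir, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(gf)
    colnames(m) <- readLines(cf)
  } else {
    delim <- if (format == "tsv") "\t" else ","
    df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    if (ncol(df) < 2) stop("malformed table (need id column + data): ", path,
                           call. = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[-1])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
      stop("parse error: non-numeric column ", names(df)[bad + 1], " in ", path,
           call. = FALSE)
    }
    rownames(m) <- ids
  }
  if (transpose) m <- t(m)
  expr_matrix(m, unit = unit, layer = "raw")
}

#' Read a cell-cycle gene catalog
#'
#' Three-column TSV `(gene, peak_stage, rank)`; `peak_stage` is one of
#' G1, G1/S, S, G2, G2/M, M (the six annotated expression peak times of the
#' curated cycle-gene catalog).
#'
#' @param path TSV path.
#' @return tibble with columns `gene_id`, `peak_stage` (factor), `rank`.
#' @export
read_gene_catalog <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1:3] <- c("gene_id", "peak_stage", "rank")
  gene_catalog(df)
}

#' Construct/validate a gene catalog
#' @param df data frame with `gene_id`, `peak_stage`, `rank`.
#' @return validated tibble of class `gene_catalog`.
#' @export
gene_catalog <- function(df) {
  stages <- c("G1", "G1/S", "S", "G2", "G2/M", "M")
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in catalog", call. = FALSE)
  if (any(is.na(df$peak_stage)) || !all(df$peak_stage %in% stages)) {
    stop("peak_stage must be one of ", paste(stages, collapse = ", "), call. = FALSE)
  }
  df$peak_stage <- factor(df$peak_stage, levels = stages)
  df$rank <- as.integer(df$rank)
  if (any(df$rank < 1)) stop("catalog ranks must be positive", call. = FALSE)
  class(df) <- c("gene_catalog", class(df))
  df
}

#' Cell quality control
#'
#' Keeps cells with strictly more than `min_genes` genes expressed strictly
#' above `min_expr` (defaults match the TPM/FPKM eligibility rule: more than
#' 4000 genes exceeding 2). For counts data supply thresholds appropriate to
#' the platform.
#'
#' @param mat raw-layer [expr_matrix()].
#' @param min_genes,min_expr strict thresholds.
#' @return list with `mat` (filtered) and `report` (a `qc_report` tibble row
#'   with `cells_in`, `cells_kept`, `genes_in`, `genes_kept` and a list-column
#'   `detected_genes` of per-cell detected-gene counts).
#' @export
qc_filter_cells <- function(mat, min_genes = 4000, min_expr = 2) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "raw") stop("cell QC expects the raw layer", call. = FALSE)
  detected <- colSums(mat$values > min_expr)
  keep <- detected > min_genes
  if (!any(keep)) stop("no eligible cells after QC (min_genes=", min_genes,
                       ", min_expr=", min_expr, ")", call. = FALSE)
  report <- tibble::tibble(
    cells_in = ncol(mat$values), cells_kept = sum(keep),
    genes_in = nrow(mat$values), genes_kept = nrow(mat$values),
    detected_genes = list(detected))
  class(report) <- c("qc_report", class(report))
  mat$values <- mat$values[, keep, drop = FALSE]
  list(mat = mat, report = report)
}

#' Gene quality control
#'
#' Drops genes whose mean expression across the kept cells is below
#' `min_mean`; the boundary is inclusive (a gene at exactly `min_mean` stays).
#'
#' @param mat raw-layer [expr_matrix()].
#' @param min_mean minimum mean expression.
#' @return filtered [expr_matrix()].
#' @export
qc_filter_genes <- function(mat, min_mean = 2) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "raw") stop("gene QC expects the raw layer", call. = FALSE)
  keep <- rowMeans(mat$values) >= min_mean
  if (!any(keep)) stop("no genes left after mean-expression filter", call. = FALSE)
  mat$values <- mat$values[keep, , drop = FALSE]
  mat
}

#' Median-of-ratios size factors
#'
#' Per-cell depth normalization: the size factor of cell j is the median over
#' reference genes of expression divided by the gene's geometric mean across
#' cells. Reference genes are those with strictly positive expression in every
#' cell (no pseudo-counting).
#'
#' @param mat raw-layer [expr_matrix()].
#' @return named numeric vector of positive per-cell factors.
#' @export
deseq_size_factors <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  v <- mat$values
  ref <- rowSums(v > 0) == ncol(v)
  if (!any(ref)) {
    stop("no gene is expressed in every cell; relax the gene QC before ",
         "computing size factors", call. = FALSE)
  }
  lg <- log(v[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, stats::median)
  names(sf) <- colnames(v)
  sf
}

#' Apply size-factor normalization
#'
#' Divides each cell's column by its size factor and advances the layer tag.
#'
#' @param mat raw-layer [expr_matrix()].
#' @param size_factors optional precomputed factors; default
#'   [deseq_size_factors()].
#' @return [expr_matrix()] with `layer = "normalized"`.
#' @export
normalize_expression <- function(mat, size_factors = NULL) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "raw") stop("normalization expects the raw layer", call. = FALSE)
  if (is.null(size_factors)) size_factors <- deseq_size_factors(mat)
  mat$values <- sweep(mat$values, 2, size_factors, "/")
  mat$layer <- "normalized"
  mat
}

#' log2(x + 1) transform
#'
#' @param mat a `normalized` (or, if the caller opts out of size factors,
#'   `raw`) [expr_matrix()].
#' @return [expr_matrix()] with `layer = "log2"`.
#' @export
log_transform <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer == "log2") stop("matrix is already log2", call. = FALSE)
  mat$values <- log2(mat$values + 1)
  mat$layer <- "log2"
  mat
}

#' Restrict a matrix to catalog genes
#'
#' Keeps the intersection of the matrix's genes with the catalog, preserving
#' the matrix's gene order. Matching is exact and case-sensitive unless
#' `ignore_case = TRUE`.
#'
#' @param mat an [expr_matrix()].
#' @param catalog a [gene_catalog()].
#' @param ignore_case fall back to case-insensitive id matching.
#' @return [expr_matrix()] restricted to catalog genes.
#' @export
subset_to_catalog <- function(mat, catalog, ignore_case = FALSE) {
  stopifnot(inherits(mat, "expr_matrix"))
  ids <- rownames(mat$values)
  hit <- if (ignore_case) tolower(ids) %in% tolower(catalog$gene_id)
         else ids %in% catalog$gene_id
  if (!any(hit)) {
    stop("no catalog genes found in the matrix; e.g. matrix has [",
         paste(utils::head(ids, 3), collapse = ", "), "] vs catalog [",
         paste(utils::head(catalog$gene_id, 3), collapse = ", "), "]",
         call. = FALSE)
  }
  mat$values <- mat$values[hit, , drop = FALSE]
  mat
}

#' Standard preprocessing chain
#'
#' QC cells, QC genes, size-factor normalize, log2-transform, and restrict to
#' the cycle-gene catalog — the default route from a raw matrix to the input
#' of clustering and ordering.
#'
#' @inheritParams qc_filter_cells
#' @inheritParams qc_filter_genes
#' @param catalog optional [gene_catalog()]; when given, genes are restricted
#'   to it after the transform.
#' @param size_normalize apply median-of-ratios normalization (default TRUE).
#' @return list with `mat` (log2 [expr_matrix()]) and `report`.
#' @export
preprocess_expression <- function(mat, catalog = NULL, min_genes = 4000,
                                  min_expr = 2, min_mean = 2,
                                  size_normalize = TRUE) {
  qc <- qc_filter_cells(mat, min_genes = min_genes, min_expr = min_expr)
  m <- qc_filter_genes(qc$mat, min_mean = min_mean)
  qc$report$genes_kept <- nrow(m$values)
  if (size_normalize) {
    m <- tryCatch(normalize_expression(m), error = function(e) {
      warning("size-factor normalization skipped: ", conditionMessage(e),
              call. = FALSE)
      m
    })
  }
  m <- log_transform(m)
  if (!is.null(catalog)) m <- subset_to_catalog(m, catalog)
  list(mat = m, report = qc$report)
}
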
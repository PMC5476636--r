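#' Binary CpG call from read counts
#'
#' Single-cell bisulfite coverage is too shallow for a rate, so a site is
#' called methylated (1) when methylated reads outnumber unmethylated ones,
#' unmethylated (0) in the opposite case, and missing (NA) on ties —
#' including the 0/0 no-evidence case.
#'
#' @param met,unmet nonnegative integer read counts (vectorized).
#' @return integer vector in `{0, 1, NA}`.
#' @export
binarize_cpg <- function(met, unmet) {
  stopifnot(all(met >= 0), all(unmet >= 0))
  out <- ifelse(met > unmet, 1L, ifelse(met < unmet, 0L, NA_integer_))
  as.integer(out)
}

#' Read a per-cell CpG coverage table
#'
#' Bismark-coverage-like TSV with columns chrom, 1-based position,
#' methylated count, unmethylated count; the binary call is added on read.
#'
#' @param path TSV path (no header).
#' @return tibble `chrom`, `pos`, `met`, `unmet`, `call`.
#' @export
read_cpg_table <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "pos", "met", "unmet"),
                        show_col_types = FALSE, progress = FALSE)
  cpg_table(df)
}

#' @rdname read_cpg_table
#' @param df data frame with `chrom`, `pos`, `met`, `unmet`.
#' @export
cpg_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (any(df$met < 0) || any(df$unmet < 0)) {
    stop("negative read counts", call. = FALSE)
  }
  df$call <- binarize_cpg(df$met, df$unmet)
  class(df) <- c("cpg_table", class(df))
  df
}

#' Genome-wide binary methylation level
#'
#' Fraction of measured sites (call 0 or 1) that are methylated; missing
#' calls are excluded from the denominator.
#'
#' @param table a [cpg_table()].
#' @return level in `[0, 1]`.
#' @export
genome_level <- function(table) {
  calls <- table$call[!is.na(table$call)]
  if (!length(calls)) stop("no measured CpG sites", call. = FALSE)
  mean(calls)
}

#' Promoter windows around transcription start sites
#'
#' Builds +/- `flank` bp windows centered on the strand-aware TSS (interval
#' start on `+`, end on `-`) of a BED6 file, clipped at position 1. BED is
#' 0-based half-open on disk; `rtracklayer` converts to 1-based closed
#' coordinates on import, matching the 1-based CpG positions.
#'
#' @param bed_path BED6 file of transcripts/genes.
#' @param flank half-window in bp (default 3000).
#' @return a `GRanges` of promoter windows with a `gene_id` column.
#' @export
tss_regions <- function(bed_path, flank = 3000L) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                GenomicRanges::end(gr), GenomicRanges::start(gr))
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(start = pmax(tss - flank, 1L),
                              end = tss + flank),
    strand = GenomicRanges::strand(gr))
  out$gene_id <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
  out
}

#' Pooled methylation level over a region set
#'
#' Site-pooled ratio: measured CpGs falling inside any region of the set are
#' pooled (each CpG counted once even under overlapping regions) and the
#' methylated fraction is returned; `NA` when no measured CpG falls in the
#' regions.
#'
#' @param table a [cpg_table()].
#' @param regions `GRanges` (e.g. from [tss_regions()]).
#' @param per_region average per-region means instead of pooling sites.
#' @return level in `[0, 1]`, or `NA`.
#' @export
region_mean_level <- function(table, regions, per_region = FALSE) {
  if (!length(regions)) stop("empty region set", call. = FALSE)
  meas <- table[!is.na(table$call), , drop = FALSE]
  if (!nrow(meas)) return(NA_real_)
  sites <- GenomicRanges::GRanges(meas$chrom,
                                  IRanges::IRanges(meas$pos, meas$pos))
  hits <- GenomicRanges::findOverlaps(sites, regions, ignore.strand = TRUE)
  if (!length(hits)) return(NA_real_)
  if (per_region) {
    by_region <- split(meas$call[S4Vectors::queryHits(hits)],
                       S4Vectors::subjectHits(hits))
    mean(vapply(by_region, mean, numeric(1)))
  } else {
    mean(meas$call[unique(S4Vectors::queryHits(hits))])
  }
}

#' Nine-point moving-average smoother
#'
#' Centered moving average with truncated windows at the edges (shrinking to
#' the available points), preserving length and range.
#'
#' @param track ordered numeric levels.
#' @param window odd window width (default 9).
#' @return smoothed vector of the same length.
#' @export
smooth9 <- function(track, window = 9L) {
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  zoo::rollapply(zoo::zoo(track), width = window, FUN = mean, partial = TRUE,
                 align = "center") |> as.numeric()
}

#' Methylation levels along the recovered cycle
#'
#' Per ordered cell, the genome-wide (or region-set) binary methylation
#' level, followed by the nine-point smoother.
#'
#' @param tables named list of per-cell [cpg_table()]s (names = cell ids).
#' @param order a `consensus_order` (or tibble with `cell_id`,
#'   `linear_rank`).
#' @param regions optional `GRanges`; when given, [region_mean_level()] is
#'   used instead of [genome_level()].
#' @param per_region passed to [region_mean_level()].
#' @param window smoother width.
#' @return a `methylation_track` tibble: `cell_id`, `rank`, `level`,
#'   `smoothed`.
#' @export
methylation_along_cycle <- function(tables, order, regions = NULL,
                                    per_region = FALSE, window = 9L) {
  ids <- order$cell_id[order(order$linear_rank)]
  miss <- setdiff(ids, names(tables))
  if (length(miss)) stop("no CpG table for cell(s): ",
                         paste(utils::head(miss, 3), collapse = ", "),
                         call. = FALSE)
  level <- vapply(ids, function(id) {
    if (is.null(regions)) genome_level(tables[[id]])
    else region_mean_level(tables[[id]], regions, per_region = per_region)
  }, numeric(1))
  sm <- level
  ok <- !is.na(level)
  sm[ok] <- smooth9(level[ok], window = window)
  out <- tibble::tibble(cell_id = ids, rank = seq_along(ids),
                        level = unname(level), smoothed = unname(sm))
  class(out) <- c("methylation_track", class(out))
  out
}
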
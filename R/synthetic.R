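#' Configuration for the cyclic expression simulator
#'
#' Defines the study conditions the generator emulates: unsynchronized cells
#' spread uniformly around the cycle, per-gene periodic mean curves whose
#' peak phases concentrate in two waves (at the G1 and G2 arcs), negative
#' binomial count noise, log-normal library-size spread, dropout, and an
#' optional quiescent (G0) subpopulation in which all cycle-gene means are
#' multiplied by a depression factor.
#'
#' @param n_cells,n_genes problem size (defaults 300 x 200).
#' @param dispersion negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param lib_sdlog log-normal sd of per-cell library-size factors.
#' @param dropout probability an observed value is zeroed.
#' @param g0_fraction fraction of cells placed in G0.
#' @param g0_depression multiplier on cycle-gene means for G0 cells.
#' @param baseline,amplitude ranges (length-2) for per-gene baseline and
#'   peak amplitude of the mean curve, in TPM-like units.
#' @param bump_kappa concentration of the periodic (von-Mises-style) bump.
#' @param seed mandatory integer seed.
#' @return a validated `cycle_sim_config` list.
#' @export
cycle_sim_config <- function(n_cells = 300L, n_genes = 200L,
                             dispersion = 0.2, lib_sdlog = 0.2,
                             dropout = 0.1, g0_fraction = 0,
                             g0_depression = 0.4,
                             baseline = c(2, 10), amplitude = c(20, 80),
                             bump_kappa = 4, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_cells >= 4, n_genes >= 2, dispersion >= 0, lib_sdlog >= 0,
            dropout >= 0, dropout < 1, g0_fraction >= 0, g0_fraction < 1,
            g0_depression > 0, g0_depression <= 1, bump_kappa > 0,
            length(baseline) == 2, length(amplitude) == 2)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 dispersion = dispersion, lib_sdlog = lib_sdlog,
                 dropout = dropout, g0_fraction = g0_fraction,
                 g0_depression = g0_depression, baseline = baseline,
                 amplitude = amplitude, bump_kappa = bump_kappa,
                 seed = as.integer(seed)),
            class = "cycle_sim_config")
}

# stage arcs on [0,1): G1 then S then G2M; sub-stages refine the same circle
stage_arcs <- list(G1 = c(0, 0.40), S = c(0.40, 0.70), G2M = c(0.70, 1))
substage_arcs <- list(`G1` = c(0, 0.25), `G1/S` = c(0.25, 0.45),
                      `S` = c(0.45, 0.60), `G2` = c(0.60, 0.78),
                      `G2/M` = c(0.78, 0.92), `M` = c(0.92, 1))

phase_to_stage <- function(phi, arcs = stage_arcs) {
  out <- character(length(phi))
  for (s in names(arcs)) {
    out[phi >= arcs[[s]][1] & phi < arcs[[s]][2]] <- s
  }
  out
}

# periodic unimodal bump with peak value 1 at phi = peak
phase_bump <- function(phi, peak, kappa) {
  exp(kappa * (cos(2 * pi * (phi - peak)) - 1))
}

#' Simulate a cyclic single-cell expression matrix
#'
#' Draws per-cell phases uniformly on the circle, builds per-gene mean
#' curves `baseline + amplitude * bump(phi - peak)` with peak phases
#' concentrated in two waves (G1 and G2 arcs), then samples negative
#' binomial observations scaled by library size, applies dropout, and
#' depresses cycle-gene means on the G0 arc. Deterministic given the config
#' seed.
#'
#' @param config a [cycle_sim_config()].
#' @return list: `mat` (raw-layer [expr_matrix()], TPM-like units), `truth`
#'   (tibble `cell_id`, `phase`, `stage`, `lib_size`), `genes` (tibble
#'   `gene_id`, `peak_phase`, `baseline`, `amplitude`, `peak_stage`),
#'   `catalog` (a [gene_catalog()] derived from the gene truth).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "cycle_sim_config"))
  set.seed(config$seed)
  n <- config$n_cells; m <- config$n_genes
  phi <- stats::runif(n)
  stage <- phase_to_stage(phi)
  n_g0 <- round(config$g0_fraction * n)
  if (n_g0 > 0) {
    g0_idx <- sample.int(n, n_g0)
    phi[g0_idx] <- stats::runif(n_g0, 0, stage_arcs$G1[2])   # park on the G1 arc
    stage[g0_idx] <- "G0"
  }
  lib <- stats::rlnorm(n, 0, config$lib_sdlog)
  # two waves of peak phases around the G1 and G2 checkpoints, plus a
  # uniform minority so every peak stage keeps marker genes
  wave <- sample(c(0.20, 0.78), m, replace = TRUE)
  peak <- (wave + stats::rnorm(m, 0, 0.07)) %% 1
  unif <- stats::runif(m) < 0.2
  peak[unif] <- stats::runif(sum(unif))
  if (m >= 6) {
    # pin one gene per annotated peak stage so all six marker sets exist
    peak[1:6] <- vapply(substage_arcs, mean, numeric(1))
  }
  baseline <- stats::runif(m, config$baseline[1], config$baseline[2])
  amplitude <- stats::runif(m, config$amplitude[1], config$amplitude[2])
  mu <- outer(seq_len(m), seq_len(n), function(g, i) {
    baseline[g] + amplitude[g] * phase_bump(phi[i], peak[g], config$bump_kappa)
  })
  if (n_g0 > 0) mu[, stage == "G0"] <- mu[, stage == "G0"] * config$g0_depression
  mu <- sweep(mu, 2, lib, "*")
  vals <- if (config$dispersion > 0) {
    matrix(stats::rnbinom(m * n, mu = mu, size = 1 / config$dispersion), m, n)
  } else {
    matrix(stats::rpois(m * n, lambda = mu), m, n)
  }
  if (config$dropout > 0) {
    vals[matrix(stats::runif(m * n) < config$dropout, m, n)] <- 0
  }
  gene_id <- sprintf("g%03d", seq_len(m))
  cell_id <- sprintf("cell%04d", seq_len(n))
  dimnames(vals) <- list(gene_id, cell_id)
  genes <- tibble::tibble(
    gene_id = gene_id, peak_phase = peak, baseline = baseline,
    amplitude = amplitude,
    peak_stage = phase_to_stage(peak, substage_arcs))
  catalog <- genes |>
    dplyr::arrange(dplyr::desc(.data$amplitude)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("gene_id", "peak_stage", "rank") |>
    gene_catalog()
  list(mat = expr_matrix(vals, unit = "TPM", layer = "raw"),
       truth = tibble::tibble(cell_id = cell_id, phase = phi, stage = stage,
                              lib_size = lib),
       genes = genes, catalog = catalog)
}

#' Simulate paired single-cell methylomes
#'
#' Per cell, a CpG coverage table over a synthetic chromosome whose global
#' methylation probability is elevated around the centre of `peak_arc`
#' (smooth periodic bump; `elevation = 0` gives a flat expected track).
#'
#' @param truth the `truth` tibble of [simulate_expression()].
#' @param peak_arc phase interval (length 2) where methylation peaks.
#' @param n_cpg expected CpG sites measured per cell.
#' @param base baseline methylation probability.
#' @param elevation added probability at the bump peak.
#' @param seed integer seed.
#' @return named list of [cpg_table()]s, one per cell.
#' @export
simulate_methylome <- function(truth, peak_arc = c(0.35, 0.55), n_cpg = 300L,
                               base = 0.3, elevation = 0.3, seed = 1L) {
  stopifnot(length(peak_arc) == 2, peak_arc[1] < peak_arc[2],
            base >= 0, base + elevation <= 1)
  set.seed(child_seed(seed, 509L))
  center <- mean(peak_arc)
  width <- peak_arc[2] - peak_arc[1]
  kappa <- 2 / width^2 * 0.1            # bump roughly spanning the arc
  tables <- lapply(seq_len(nrow(truth)), function(i) {
    p <- base + elevation * phase_bump(truth$phase[i], center, kappa)
    ns <- stats::rpois(1, n_cpg)
    pos <- sort(sample.int(1e6, ns))
    cov <- 1L + stats::rpois(ns, 2)
    met <- stats::rbinom(ns, cov, p)
    cpg_table(tibble::tibble(chrom = "chr1", pos = pos, met = met,
                             unmet = cov - met))
  })
  stats::setNames(tables, truth$cell_id)
}

#' Write a complete fixture bundle to disk
#'
#' Simulates expression (and optionally methylomes) and writes every file
#' dialect the readers consume: dense TSV and MatrixMarket expression with
#' sidecars, catalog TSV, stage-label TSV, per-cell CpG tables, a BED6 file
#' of synthetic gene loci, and the ground-truth JSON.
#'
#' @param dir output directory (created if needed).
#' @param config a [cycle_sim_config()].
#' @param methylome also write per-cell CpG tables and the BED file.
#' @return invisibly, the list of written paths.
#' @export
write_fixture_bundle <- function(dir, config, methylome = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(config)
  paths <- list()
  expr_df <- tibble::as_tibble(sim$mat$values, rownames = "gene_id")
  paths$expr_tsv <- file.path(dir, "expression.tsv")
  readr::write_tsv(expr_df, paths$expr_tsv, progress = FALSE)
  paths$expr_mtx <- file.path(dir, "expression.mtx")
  Matrix::writeMM(Matrix::Matrix(sim$mat$values, sparse = TRUE),
                  paths$expr_mtx)
  writeLines(rownames(sim$mat$values), file.path(dir, "genes.txt"))
  writeLines(colnames(sim$mat$values), file.path(dir, "cells.txt"))
  paths$catalog <- file.path(dir, "catalog.tsv")
  readr::write_tsv(tibble::as_tibble(sim$catalog), paths$catalog,
                   progress = FALSE)
  paths$labels <- file.path(dir, "labels.tsv")
  readr::write_tsv(sim$truth[, c("cell_id", "stage")], paths$labels,
                   progress = FALSE)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(cells = sim$truth, genes = sim$genes,
                            seed = config$seed),
                       paths$truth, digits = NA, auto_unbox = TRUE)
  if (methylome) {
    tabs <- simulate_methylome(sim$truth, seed = config$seed)
    cpg_dir <- file.path(dir, "cpg")
    dir.create(cpg_dir, showWarnings = FALSE)
    for (id in names(tabs)) {
      readr::write_tsv(tabs[[id]][, c("chrom", "pos", "met", "unmet")],
                       file.path(cpg_dir, paste0(id, ".tsv")),
                       col_names = FALSE, progress = FALSE)
    }
    paths$cpg_dir <- cpg_dir
    set.seed(child_seed(config$seed, 211L))
    tss <- sort(sample.int(1e6 - 6000, 20)) + 3000
    bed <- tibble::tibble(chrom = "chr1", start = tss - 500L, end = tss + 500L,
                          name = sprintf("g%03d", seq_along(tss)), score = 0L,
                          strand = sample(c("+", "-"), 20, replace = TRUE))
    paths$bed <- file.path(dir, "genes.bed")
    readr::write_tsv(bed, paths$bed, col_names = FALSE, progress = FALSE)
  }
  invisible(paths)
}
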
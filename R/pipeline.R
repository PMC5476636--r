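#' Assemble a run configuration
#'
#' All paths, thresholds and seeds of an end-to-end run in one serializable
#' list; `read_run_config()` loads the same structure from YAML.
#'
#' @param expression path to the expression matrix.
#' @param catalog path to the gene catalog TSV.
#' @param out_dir artifact directory.
#' @param format,unit,transpose passed to [read_expression()].
#' @param labels optional stage-label TSV (enables training the gene-pair
#'   model on the data and the evaluation outputs).
#' @param cpg_dir optional directory of per-cell CpG tables
#'   (`<cell_id>.tsv`).
#' @param bed optional BED6 file for promoter windows.
#' @param min_genes,min_expr,min_mean QC thresholds.
#' @param k_min,k_max,n_fold,n_init ordering parameters.
#' @param include_g0 add a G0 state to the HMM.
#' @param granularity score granularity (`"cell"` or `"cluster"`).
#' @param n_perm association permutations.
#' @param smooth_assoc smooth series before association testing.
#' @param fast_start reuse one HMM fit across rotations in [find_start()].
#' @param pair_model optional path to a serialized gene-pair model (used
#'   when no labels are given; default: the synthetic-trained model shipped
#'   with the package).
#' @param seed master seed for every randomized stage.
#' @return a `run_config` list.
#' @export
run_config <- function(expression, catalog, out_dir, format = "tsv",
                       unit = "TPM", transpose = FALSE, labels = NULL,
                       cpg_dir = NULL, bed = NULL, min_genes = 4000L,
                       min_expr = 2, min_mean = 2, k_min = 7L, k_max = NULL,
                       n_fold = 2L, n_init = 5L, include_g0 = FALSE,
                       granularity = "cell", n_perm = 0L,
                       smooth_assoc = FALSE, fast_start = TRUE,
                       pair_model = NULL, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file with the fields of [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full workflow
#'
#' Ingest and preprocess, recover the consensus circular order, compute the
#' nine-dimensional score track, segment stages with the HMM (with start /
#' orientation search), rank cycle-associated genes, optionally overlay
#' methylation and evaluate against labels. Writes TSV artifacts plus a
#' manifest (config hash, seeds, per-k tour lengths) and returns the results
#' invisibly.
#'
#' @param config a [run_config()] (or path to its YAML).
#' @return invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  step <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  raw <- step("ingest", read_expression(config$expression, config$format,
                                        config$unit, config$transpose))
  catalog <- step("catalog", read_gene_catalog(config$catalog))
  prep <- step("preprocess",
               preprocess_expression(raw, catalog = NULL,
                                     min_genes = config$min_genes,
                                     min_expr = config$min_expr,
                                     min_mean = config$min_mean))
  full <- prep$mat                        # all genes, log2: gene ranking input
  cyc <- step("subset", subset_to_catalog(full, catalog))

  ord <- step("order",
              consensus_order(cyc, k_min = config$k_min, k_max = config$k_max,
                              n_fold = config$n_fold, seed = config$seed,
                              n_init = config$n_init))
  readr::write_tsv(tibble::as_tibble(ord), file.path(config$out_dir, "order.tsv"),
                   progress = FALSE)

  labels <- NULL
  if (!is.null(config$labels)) labels <- read_stage_labels(config$labels)
  model <- step("pair_model", {
    if (!is.null(labels) &&
        all(c("G1", "S", "G2M") %in% unique(labels$stage))) {
      lab <- stats::setNames(as.character(labels$stage), labels$cell_id)
      lab[lab == "G0"] <- "G1"
      train_gene_pairs(cyc, lab[cell_ids(cyc)])
    } else if (!is.null(config$pair_model)) {
      subset_pair_model(read_gene_pair_model(config$pair_model),
                        gene_ids(cyc))
    } else {
      subset_pair_model(
        read_gene_pair_model(system.file("extdata",
                                         "gene_pair_model_synthetic.json",
                                         package = "cyclotour")),
        gene_ids(cyc))
    }
  })
  sets <- mean_score_sets(catalog)
  track <- step("scores", score_track(ord, cyc, model, sets,
                                      granularity = config$granularity))
  readr::write_tsv(tibble::as_tibble(track),
                   file.path(config$out_dir, "scores.tsv"), progress = FALSE)

  start <- step("start_search",
                find_start(track, include_g0 = config$include_g0,
                           seed = config$seed, refit = !config$fast_start))
  stages <- step("stages", viterbi_stages(start$hmm, track, start$rotation,
                                          start$orientation))
  readr::write_tsv(tibble::as_tibble(stages),
                   file.path(config$out_dir, "stages.tsv"), progress = FALSE)

  assoc <- step("genes", rank_cycle_genes(full, ord, n_perm = config$n_perm,
                                          seed = config$seed,
                                          smooth = config$smooth_assoc))
  readr::write_tsv(assoc, file.path(config$out_dir, "genes.tsv"),
                   progress = FALSE)

  meth <- NULL
  if (!is.null(config$cpg_dir)) {
    meth <- step("methylation", {
      files <- list.files(config$cpg_dir, pattern = "\\.tsv$",
                          full.names = TRUE)
      tabs <- stats::setNames(lapply(files, read_cpg_table),
                              sub("\\.tsv$", "", basename(files)))
      regions <- if (!is.null(config$bed)) tss_regions(config$bed) else NULL
      methylation_along_cycle(tabs, ord, regions = regions)
    })
    readr::write_tsv(meth, file.path(config$out_dir, "methylation.tsv"),
                     progress = FALSE)
  }

  evaluation <- NULL
  if (!is.null(labels)) {
    evaluation <- step("evaluate", {
      lab <- stats::setNames(as.character(labels$stage), labels$cell_id)
      num <- label_numbers(lab[ord$cell_id])
      lin <- num[order(ord$linear_rank)]
      list(correlation_score = correlation_score(ord, num),
           change_index = change_index(lin), n = nrow(ord), k = nrow(ord))
    })
    jsonlite::write_json(evaluation, file.path(config$out_dir, "evaluation.json"),
                         digits = NA, auto_unbox = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cyclotour")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    provenance = attr(ord, "provenance"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(list(order = ord, track = track, stages = stages, hmm = start$hmm,
                 associations = assoc, methylation = meth,
                 evaluation = evaluation, report = prep$report))
}
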
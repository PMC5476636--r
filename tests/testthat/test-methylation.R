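test_that("binary CpG calls follow the majority rule with ties missing", {
  expect_equal(binarize_cpg(3, 1), 1L)
  expect_equal(binarize_cpg(1, 3), 0L)
  expect_equal(binarize_cpg(0, 0), NA_integer_)
  expect_equal(binarize_cpg(2, 2), NA_integer_)
  expect_equal(binarize_cpg(c(3, 0, 2), c(1, 0, 2)),
               c(1L, NA_integer_, NA_integer_))
})

test_that("genome level counts measured sites only", {
  tab <- cpg_table(tibble::tibble(chrom = "chr1", pos = c(10, 20, 30, 40),
                                  met = c(2, 3, 0, 1), unmet = c(0, 1, 2, 1)))
  expect_equal(genome_level(tab), 2 / 3)     # calls 1, 1, 0, NA
  all1 <- cpg_table(tibble::tibble(chrom = "chr1", pos = 1:3, met = 2,
                                   unmet = 0))
  expect_equal(genome_level(all1), 1)
  none <- cpg_table(tibble::tibble(chrom = "chr1", pos = 1, met = 1,
                                   unmet = 1))
  expect_error(genome_level(none), "no measured")
  # shard/merge invariance
  merged <- cpg_table(dplyr::bind_rows(tab[1:2, 1:4], tab[3:4, 1:4]))
  expect_equal(genome_level(merged), genome_level(tab))
})

test_that("region levels pool sites and never double-count overlaps", {
  tab <- cpg_table(tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                                  pos = c(100, 200, 50),
                                  met = c(3, 0, 5), unmet = c(1, 2, 0)))
  r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 250))
  expect_equal(region_mean_level(tab, r1), 0.5)      # calls 1 and 0
  # duplicated overlapping regions: same answer
  r2 <- c(r1, GenomicRanges::GRanges("chr1", IRanges::IRanges(80, 220)))
  expect_equal(region_mean_level(tab, r2), 0.5)
  # region on an absent chromosome -> missing
  r3 <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 1000))
  expect_true(is.na(suppressWarnings(region_mean_level(tab, r3))))
  # per-region averaging is exposed behind a flag
  r4 <- c(GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 110)),
          GenomicRanges::GRanges("chr1", IRanges::IRanges(190, 210)))
  expect_equal(region_mean_level(tab, r4, per_region = TRUE), 0.5)
})

test_that("TSS windows are strand-aware and clipped", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t2000\tgPlus\t0\t+",
               "chr1\t5000\t6000\tgMinus\t0\t-",
               "chr1\t100\t900\tgEdge\t0\t+"), bed)
  gr <- tss_regions(bed, flank = 3000)
  # + strand TSS = 0-based start 1000 -> 1-based 1001
  expect_equal(GenomicRanges::start(gr)[1], 1)       # 1001 - 3000 clipped
  expect_equal(GenomicRanges::end(gr)[1], 4001)
  # - strand TSS = end = 6000
  expect_equal(GenomicRanges::start(gr)[2], 3000)
  expect_equal(GenomicRanges::end(gr)[2], 9000)
  expect_equal(gr$gene_id, c("gPlus", "gMinus", "gEdge"))
})

test_that("the nine-point smoother preserves constants, ramps and range", {
  expect_equal(smooth9(rep(0.4, 20)), rep(0.4, 20))
  ramp <- 1:20
  sm <- smooth9(ramp)
  expect_equal(sm[10], 10)                # interior of a ramp is unchanged
  expect_equal(length(smooth9(c(0.2, 0.8, 0.5))), 3)
  set.seed(5)
  x <- runif(40)
  s <- smooth9(x)
  expect_true(all(s >= min(x) - 1e-12 & s <= max(x) + 1e-12))
  expect_error(smooth9(x, window = 4), "odd")
})

test_that("methylation tracks follow the pseudotime, not the file order", {
  truth <- tibble::tibble(cell_id = sprintf("c%02d", 1:40),
                          phase = (seq_len(40) - 0.5) / 40)
  tabs <- simulate_methylome(truth, peak_arc = c(0.35, 0.55), n_cpg = 250,
                             seed = 3)
  ord <- tibble::tibble(cell_id = truth$cell_id, linear_rank = seq_len(40))
  tr <- methylation_along_cycle(tabs, ord)
  expect_equal(nrow(tr), 40)
  expect_true(all(tr$level >= 0 & tr$level <= 1, na.rm = TRUE))
  # smoothed peak falls inside the elevated arc
  peak_phase <- truth$phase[which.max(tr$smoothed)]
  expect_gte(peak_phase, 0.3)
  expect_lte(peak_phase, 0.6)
  # permuting the input list leaves the track unchanged (keyed by id)
  tr2 <- methylation_along_cycle(rev(tabs), ord)
  expect_equal(tr2, tr)
  # identical tables give a flat track
  same <- stats::setNames(rep(tabs[1], 40), truth$cell_id)
  tr3 <- methylation_along_cycle(same, ord)
  expect_equal(diff(range(tr3$smoothed)), 0)
})
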
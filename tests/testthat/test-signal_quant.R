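test_that("compute_fpkm matches the closed form and a brute-force oracle", {
  genes <- data.frame(gene_id = c("g1", "g2"), gene_length = c(1000L, 2000L))
  samples <- data.frame(sample_id = c("s1", "s2"), condition = "control",
                        assay = "rna", library_size = c(1e6, 2e6))
  counts <- matrix(c(10L, 0L, 20L, 40L), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fpkm <- compute_fpkm(counts, genes, samples)
  expect_equal(fpkm["g1", "s1"], 10)      # 10 * 1e9 / (1000 * 1e6)
  expect_equal(fpkm["g2", "s1"], 0)
  expect_equal(fpkm["g1", "s2"], 10)      # 20 * 1e9 / (1000 * 2e6)

  # random 50 x 4 vs element-wise formula evaluation
  set.seed(11)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:50),
                      gene_length = sample(500:30000, 50))
  samples <- make_sample_sheet(2, "rna")
  samples$library_size <- sample(1e6:5e7, 4)
  counts <- matrix(rpois(200, 50), 50,
                   dimnames = list(genes$gene_id, samples$sample_id))
  fpkm <- compute_fpkm(counts, genes, samples)
  for (i in sample(50, 10)) {
    for (j in 1:4) {
      expect_equal(fpkm[i, j],
                   counts[i, j] * 1e9 /
                     (as.numeric(genes$gene_length[i]) *
                        samples$library_size[j]))
    }
  }
  # linearity in counts at fixed length and library size
  expect_equal(compute_fpkm(counts * 3L, genes, samples), fpkm * 3)
})

test_that("compute_fpkm rejects missing annotation or samples", {
  genes <- data.frame(gene_id = "g1", gene_length = 1000L)
  samples <- data.frame(sample_id = "s1", condition = "control",
                        assay = "rna", library_size = 1e6)
  counts <- matrix(1L, 1, 1, dimnames = list("gX", "s1"))
  expect_error(compute_fpkm(counts, genes, samples), "missing from annotation")
  counts <- matrix(1L, 1, 1, dimnames = list("g1", "sX"))
  expect_error(compute_fpkm(counts, genes, samples),
               "missing from sample sheet")
})

local({
  peaks <- data.frame(peak_id = c("p1", "p2"), chrom = "chr1",
                      start = c(0L, 1000L), end = c(500L, 2000L),
                      source_line = 1:2)
  sheet <- data.frame(
    sample_id = c("c1", "i1"), condition = "control",
    assay = c("chip", "input"), library_size = c(1e6, 1e6))
  pairing <- c(c1 = "i1")
  mk <- function(c1, c2, ids = c("p1", "p2"), sample = "c1") {
    matrix(as.integer(c(c1, c2)), 2, dimnames = list(ids, sample))
  }

  test_that("normalize_peak_signal evaluates the closed form", {
    sig <- normalize_peak_signal(mk(100, 0), mk(50, 10, sample = "i1"),
                                 peaks, sheet, pairing)
    # c=100, N=1e6, L=500: dens_chip = 100*1e9/(1e6*500) = 200; input 100
    expect_equal(sig["p1", "c1"], 100)
    expect_equal(sig["p2", "c1"], 0)     # chip 0, input 10 -> floored
    meta <- attr(sig, "normalization_meta")
    expect_equal(meta$scale_constant, 1e9)
    expect_equal(unname(meta$per_sample$c1["beta"]), 1)
  })

  test_that("equal normalized densities cancel; floor keeps signal >= 0", {
    sheet2 <- sheet
    sheet2$library_size <- c(2e6, 1e6)
    sig <- normalize_peak_signal(mk(200, 30), mk(100, 40, sample = "i1"),
                                 peaks, sheet2, pairing)
    expect_equal(sig["p1", "c1"], 0)   # 200/2e6 == 100/1e6
    expect_equal(sig["p2", "c1"], 0)   # 30/2e6 < 40/1e6, floored
    expect_true(all(sig >= 0))
  })

  test_that("scaling a sample's counts and library together is a no-op", {
    chip <- mk(137, 81)
    input <- mk(52, 9, sample = "i1")
    base <- normalize_peak_signal(chip, input, peaks, sheet, pairing)
    sheet3 <- sheet
    sheet3$library_size[1] <- sheet3$library_size[1] * 7
    scaled <- normalize_peak_signal(chip * 7L, input, peaks, sheet3, pairing)
    expect_equal(scaled, base, ignore_attr = TRUE)
  })

  test_that("doubling peak length and counts preserves density; zero input
             passes chip density through", {
    peaks2 <- peaks
    peaks2$end[1] <- peaks2$start[1] + 1000L  # doubled p1
    base <- normalize_peak_signal(mk(100, 50), mk(0, 0, sample = "i1"),
                                  peaks, sheet, pairing)
    doubled <- normalize_peak_signal(mk(200, 50), mk(0, 0, sample = "i1"),
                                     peaks2, sheet, pairing)
    expect_equal(doubled["p1", "c1"], base["p1", "c1"])
    # all-zero input: signal equals dens_chip exactly
    expect_equal(base["p1", "c1"], 100 * 1e9 / (1e6 * 500))
  })

  test_that("unpaired samples and unknown peaks are rejected", {
    expect_error(
      normalize_peak_signal(mk(1, 1), mk(1, 1, sample = "i1"), peaks, sheet,
                            c(cX = "i1")),
      "unpaired")
    expect_error(
      normalize_peak_signal(mk(1, 1, ids = c("p1", "pZ")),
                            mk(1, 1, ids = c("p1", "pZ"), sample = "i1"),
                            peaks, sheet, pairing),
      "missing from peak list")
  })
})

test_that("background scale factor is the median of per-bin ratios", {
  sheet <- data.frame(sample_id = c("c1", "i1"), condition = "control",
                      assay = c("chip", "input"), library_size = c(1e6, 1e6))
  bins <- matrix(as.integer(c(4, 10, 6)), 3,
                 dimnames = list(paste0("b", 1:3), "i1"))
  chip2x <- matrix(as.integer(c(8, 20, 12)), 3,
                   dimnames = list(paste0("b", 1:3), "c1"))
  est <- estimate_background_scale(chip2x, bins, sheet, c(c1 = "i1"))
  expect_equal(est$scale_factor, 2)
  expect_equal(est$n_bins_used, 3L)

  same <- chip2x; same[] <- bins
  est1 <- estimate_background_scale(same, bins, sheet, c(c1 = "i1"))
  expect_equal(est1$scale_factor, 1)

  # Poisson-simulated bins vs an independently computed median of ratios
  set.seed(21)
  n <- 4000
  ib <- matrix(rpois(n, 8), n, dimnames = list(sprintf("b%04d", 1:n), "i1"))
  cb <- matrix(rpois(n, 12), n, dimnames = list(sprintf("b%04d", 1:n), "c1"))
  sheet$library_size <- c(3e6, 2e6)
  est2 <- estimate_background_scale(cb, ib, sheet, c(c1 = "i1"))
  keep <- ib[, 1] > 0
  expect_equal(est2$scale_factor,
               median((cb[keep, 1] / 3e6) / (ib[keep, 1] / 2e6)))
  expect_equal(est2$n_bins_used, sum(keep))

  ib0 <- ib; ib0[] <- 0L
  expect_error(estimate_background_scale(cb, ib0, sheet, c(c1 = "i1")),
               "no background bin")
})

test_that("background estimate rescales input in normalization", {
  peaks <- data.frame(peak_id = "p1", chrom = "chr1", start = 0L, end = 1000L,
                      source_line = 1L)
  sheet <- data.frame(sample_id = c("c1", "i1"), condition = "control",
                      assay = c("chip", "input"), library_size = c(1e6, 1e6))
  chip <- matrix(300L, 1, dimnames = list("p1", "c1"))
  input <- matrix(100L, 1, dimnames = list("p1", "i1"))
  bg <- data.frame(sample_id = "c1", input_sample_id = "i1",
                   scale_factor = 2, n_bins_used = 10L,
                   bin_width = 20L, region_span = 1e6L)
  sig <- normalize_peak_signal(chip, input, peaks, sheet, c(c1 = "i1"),
                               background = bg)
  expect_equal(sig["p1", "c1"], (300 - 2 * 100) * 1e9 / (1e6 * 1000))
})

test_that("quantify_bam_over_intervals sums per-base depth like bedcov", {
  skip_if_not_installed("Rsamtools")
  # 3-read toy alignment written as SAM text, converted at test time
  seq100 <- strrep("A", 100)
  qual100 <- strrep("I", 100)
  rd <- function(id, pos) {
    paste(id, 0, "chr1", pos, 60, "100M", "*", 0, 0, seq100, qual100,
          sep = "\t")
  }
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chr1\tLN:1000",
           rd("r1", 1),     # covers 50 bp of interval [51, 150]
           rd("r2", 201),   # r2+r3: two contained 100 bp reads in [201, 400]
           rd("r3", 301))
  dir <- withr::local_tempdir()
  sam_path <- file.path(dir, "toy.sam")
  writeLines(sam, sam_path)
  bam_path <- Rsamtools::asBam(sam_path, file.path(dir, "toy"),
                               overwrite = TRUE, indexDestination = TRUE)
  intervals <- data.frame(
    peak_id = c("cov50", "cov200", "empty"),
    chrom = "chr1",
    start = c(50L, 200L, 600L),   # 0-based half-open
    end = c(150L, 400L, 700L),
    source_line = 1:3)
  counts <- quantify_bam_over_intervals(bam_path, intervals)
  expect_equal(counts, c(cov50 = 50L, cov200 = 200L, empty = 0L))

  bad <- intervals; bad$chrom <- "chrMissing"
  expect_error(quantify_bam_over_intervals(bam_path, bad), "chrMissing")
  file.remove(paste0(bam_path, ".bai"))
  expect_error(quantify_bam_over_intervals(bam_path, intervals), "index")
})
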
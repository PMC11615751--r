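test_that("TSS-window linking handles containment, boundaries, chromosomes", {
  w <- 1000000L
  peaks <- data.frame(peak_id = "p1", chrom = "chr1", start = 100L,
                      end = 200L, source_line = 1L)
  mk_gene <- function(tss, chrom = "chr1") {
    data.frame(gene_id = "g1", chrom = chrom, start = tss, end = tss + 1000L,
               strand = "+", tss = tss, gene_length = 1000L)
  }
  inside <- link_peaks_to_genes(peaks, mk_gene(150L), w)
  expect_equal(inside$distance_bp, 0L)
  at_edge_minus1 <- link_peaks_to_genes(peaks, mk_gene(200L + w - 1L), w)
  expect_equal(at_edge_minus1$distance_bp, w - 1L)
  at_edge <- link_peaks_to_genes(peaks, mk_gene(200L + w), w)
  expect_equal(at_edge$distance_bp, w)            # boundary inclusive
  expect_equal(nrow(link_peaks_to_genes(peaks, mk_gene(200L + w + 1L), w)),
               0L)
  expect_equal(nrow(link_peaks_to_genes(peaks, mk_gene(150L, "chr2"), w)),
               0L)
  upstream <- link_peaks_to_genes(peaks, mk_gene(100L - 500L), w)
  expect_equal(upstream$distance_bp, 500L)
})

test_that("linking equals the brute-force all-pairs scan", {
  peaks <- random_peaks(30, seed = 81)
  genes <- random_genes(40, seed = 82)
  for (w in c(0L, 1000L, 250000L, 2000000L)) {
    got <- link_peaks_to_genes(peaks, genes, w)
    expect_equal(got, brute_force_links(peaks, genes, w), info = paste(w))
  }
  # monotone in window: enlarging never drops a link
  small <- link_peaks_to_genes(peaks, genes, 100000L)
  large <- link_peaks_to_genes(peaks, genes, 400000L)
  expect_true(all(paste(small$peak_id, small$gene_id) %in%
                    paste(large$peak_id, large$gene_id)))
})

local({
  cfg <- integration_config()
  sig <- rbind(pA = c(1, 2, 3, 4, 5, 6),
               pB = c(2, 2, 2, 2, 2, 2),
               pC = c(6, 5, 4, 3, 2, 1))
  colnames(sig) <- paste0("s", 1:6)
  expr <- rbind(gA = c(1, 2, 3, 4, 5, 6),
                gB = c(1.5, 2.1, 2.9, 4.2, 5.1, 5.8),
                gC = c(10, 20, 15, 40, 5, 60))
  colnames(expr) <- paste0("s", 1:6)

  test_that("correlate_links fills r/p and flags zero-variance rows", {
    links <- data.frame(peak_id = c("pA", "pB", "pC"),
                        gene_id = c("gA", "gA", "gA"),
                        distance_bp = 0L, stringsAsFactors = FALSE)
    out <- correlate_links(links, sig, expr, paste0("s", 1:6), config = cfg)
    expect_equal(out$pearson_r[1], 1)
    expect_true(out$correlated[1])
    expect_true(is.na(out$pearson_r[2]))        # constant signal row
    expect_false(out$correlated[2])
    expect_equal(out$pearson_r[3], -1)
    expect_true(out$correlated[3])              # |r| reading admits negatives
    signed <- correlate_links(links, sig, expr, paste0("s", 1:6),
                              config = integration_config(signed_r = TRUE))
    expect_false(signed$correlated[3])
  })

  test_that("correlate_links agrees with direct pearson_corr composition", {
    links <- expand.grid(peak_id = c("pA", "pC"), gene_id = c("gB", "gC"),
                         stringsAsFactors = FALSE)
    links$distance_bp <- 0L
    out <- correlate_links(links, sig, expr, paste0("s", 1:6), config = cfg)
    for (i in seq_len(nrow(out))) {
      ref <- pearson_corr(sig[out$peak_id[i], ], expr[out$gene_id[i], ])
      expect_equal(out$pearson_r[i], ref$r)
      expect_equal(out$pearson_p[i], ref$p_value)
    }
  })

  test_that("correlate_links validates the shared sample order", {
    links <- data.frame(peak_id = "pA", gene_id = "gA", distance_bp = 0L)
    expect_error(correlate_links(links, sig, expr, paste0("s", 1:7)),
                 "mismatch")
    expect_error(correlate_links(links, sig, expr, c("s1", "s2")), ">= 3")
  })
})

test_that("quadrant classification matches the four-way sign partition", {
  cfg <- integration_config()   # chip threshold 1, rna threshold 5, strict
  cases <- data.frame(
    chip_log2fc = c(2, -2, 2, -2, 1, 0.5, 2, -2, 0, 1.01),
    rna_log2fc = c(6, -6, -6, 6, 6, 6, 5, -5, 0, 5.01))
  cases$expected <- c("PP", "NN", "PN", "NP", "NS", "NS", "NS", "NS", "NS",
                      "PP")
  cases$peak_id <- sprintf("p%02d", seq_len(nrow(cases)))
  cases$gene_id <- sprintf("g%02d", seq_len(nrow(cases)))
  got <- classify_quadrants(cases, cfg)
  expect_equal(got$quadrant, cases$expected)
})

test_that("quadrant partition is exhaustive and antisymmetric", {
  cfg <- integration_config()
  grid <- expand.grid(chip_log2fc = c(-3, -1.5, -1, -0.5, 0, 0.5, 1, 1.5, 3),
                      rna_log2fc = c(-8, -5.5, -5, -2, 0, 2, 5, 5.5, 8))
  grid$peak_id <- sprintf("p%02d", seq_len(nrow(grid)))
  grid$gene_id <- grid$peak_id
  got <- classify_quadrants(grid, cfg)
  expect_true(all(got$quadrant %in% c("PP", "NN", "PN", "NP", "NS")))
  # independent re-derivation from the printed rule
  ref <- with(grid, ifelse(chip_log2fc > 1 & rna_log2fc > 5, "PP",
              ifelse(chip_log2fc < -1 & rna_log2fc < -5, "NN",
              ifelse(chip_log2fc > 1 & rna_log2fc < -5, "PN",
              ifelse(chip_log2fc < -1 & rna_log2fc > 5, "NP", "NS")))))
  expect_equal(got$quadrant, ref)
  # negating both fold changes swaps PP<->NN and PN<->NP
  neg <- grid
  neg$chip_log2fc <- -neg$chip_log2fc
  neg$rna_log2fc <- -neg$rna_log2fc
  swapped <- classify_quadrants(neg, cfg)$quadrant
  map <- c(PP = "NN", NN = "PP", PN = "NP", NP = "PN", NS = "NS")
  expect_equal(swapped, unname(map[got$quadrant]))
})

test_that("quadrant summary recounts the classified links", {
  links <- data.frame(
    peak_id = sprintf("p%03d", 1:120), gene_id = sprintf("g%03d", 1:120),
    quadrant = sample(c("PP", "NN", "PN", "NP", "NS"), 120, replace = TRUE))
  s <- quadrant_summary(links)
  expect_equal(s$total_classified, sum(links$quadrant != "NS"))
  expect_equal(unname(s$counts["NN"]), sum(links$quadrant == "NN"))
  expect_equal(s$total_classified + s$ns, nrow(links))
  empty <- links[0, ]
  s0 <- quadrant_summary(empty)
  expect_equal(s0$total_classified, 0L)
  expect_equal(unname(s0$counts), rep(0L, 4))
})

test_that("ranking orders by |chip|*|rna| with documented tie-breaks", {
  set.seed(91)
  n <- 25
  links <- data.frame(
    peak_id = sprintf("p%02d", sample(n)), gene_id = sprintf("g%02d", 1:n),
    chip_log2fc = round(runif(n, -4, 4), 1),
    rna_log2fc = round(runif(n, -8, 8), 1),
    pearson_r = round(runif(n, -1, 1), 2),
    pearson_p = runif(n, 0, 0.04),
    correlated = rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 5),
    stringsAsFactors = FALSE)
  links <- classify_quadrants(links, integration_config())
  top <- rank_top_peak_genes(links, k = 10)
  # independent full sort of the qualifying pool
  pool <- links[links$quadrant %in% c("PP", "NN") & links$correlated, ]
  score <- abs(pool$chip_log2fc) * abs(pool$rna_log2fc)
  ord <- order(-score, -abs(pool$pearson_r), pool$peak_id, pool$gene_id)
  expect_equal(top$peak_id, head(pool$peak_id[ord], 10))
  expect_true(all(diff(top$score) <= 0))
  # stable under permutation of the input rows
  perm <- sample(nrow(links))
  top2 <- rank_top_peak_genes(links[perm, ], k = 10)
  expect_equal(top2$peak_id, top$peak_id)
  expect_error(rank_top_peak_genes(links, k = 0), "positive")
})
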
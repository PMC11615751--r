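# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the code paths they check.

make_sample_sheet <- function(n = 3, assay = "rna", lib = 1e7) {
  data.frame(sample_id = sprintf("%s_%s_%d", assay,
                                 rep(c("control", "case"), each = n),
                                 rep(seq_len(n), 2)),
             condition = rep(c("control", "case"), each = n),
             assay = assay,
             library_size = lib,
             stringsAsFactors = FALSE)
}

write_tsv_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force all-pairs TSS-window linker (double loop, no interval trees)
brute_force_links <- function(peaks, genes, window_bp) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      tss <- genes$tss[j]
      d <- if (tss < peaks$start[i]) peaks$start[i] - tss
           else if (tss >= peaks$end[i]) tss - peaks$end[i]
           else 0L
      if (d <= window_bp) {
        rows[[length(rows) + 1L]] <-
          data.frame(peak_id = peaks$peak_id[i], gene_id = genes$gene_id[j],
                     distance_bp = as.integer(d), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$peak_id, out$distance_bp, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact hypergeometric upper tail by enumeration of all draws (universe <= 12)
brute_force_hyper <- function(universe_size, set_size, query_size, overlap) {
  draws <- combn(universe_size, query_size)
  annotated <- seq_len(set_size)   # which universe elements are in the set
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= overlap)
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), seed = 1) {
  set.seed(seed)
  start <- sort(sample.int(5e6, n))
  width <- sample(200:1500, n, replace = TRUE)
  data.frame(peak_id = sprintf("pk%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             source_line = seq_len(n), stringsAsFactors = FALSE)
}

random_genes <- function(n, chroms = c("chr1", "chr2"), seed = 2) {
  set.seed(seed)
  tss <- sample.int(6e6, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- sample(1000:20000, n, replace = TRUE)
  start <- ifelse(strand == "+", tss, tss - len + 1L)
  data.frame(gene_id = sprintf("gn%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = as.integer(start), end = as.integer(start + len),
             strand = strand, tss = as.integer(tss),
             gene_length = as.integer(len), stringsAsFactors = FALSE)
}
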
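# The core integrative procedure: link peaks to genes by a TSS window,
# correlate normalized peak signal with gene expression across samples,
# classify linked pairs into PP/NN/PN/NP fold-change quadrants, and rank the
# top peak-genes.

#' Integration thresholds
#'
#' Bundles the tunable thresholds of the integrative stage: the TSS linking
#' window, the correlation criterion (|r| >= `r_min` and p < `p_max`), and
#' the fold-change quadrant thresholds (strict: ChIP |log2FC| > `chip_lfc_min`
#' and RNA |log2FC| > `rna_lfc_min`).
#'
#' @param window_bp TSS-to-peak-edge window in bp (default 1e6: a gene is a
#'   candidate target if its TSS lies within 1 Mb of the nearest peak edge).
#' @param r_min Minimum correlation magnitude (default 0.5).
#' @param p_max Maximum correlation p-value (default 0.05).
#' @param chip_lfc_min ChIP log2 fold-change threshold (default 1).
#' @param rna_lfc_min RNA log2 fold-change threshold (default 5).
#' @param signed_r If `TRUE`, the correlation criterion uses signed r
#'   (`r >= r_min`) instead of `|r| >= r_min`; the default absolute reading
#'   lets negatively-correlated PN/NP pairs qualify as correlated.
#' @return A list of class `integration_config`.
#' @export
integration_config <- function(window_bp = 1000000L, r_min = 0.5,
                               p_max = 0.05, chip_lfc_min = 1,
                               rna_lfc_min = 5, signed_r = FALSE) {
  stopifnot(window_bp >= 0, r_min > 0, p_max > 0, p_max < 1,
            chip_lfc_min > 0, rna_lfc_min > 0)
  structure(list(window_bp = as.integer(window_bp), r_min = r_min,
                 p_max = p_max, chip_lfc_min = chip_lfc_min,
                 rna_lfc_min = rna_lfc_min, signed_r = signed_r),
            class = "integration_config")
}

#' Link peaks to genes whose TSS lies within a window
#'
#' Emits every (peak, gene) pair on the same chromosome whose strand-aware
#' TSS lies within `window_bp` of the peak (boundary inclusive). The distance
#' is 0 when the TSS falls inside the half-open peak interval, otherwise the
#' gap between the TSS and the nearest peak edge. The mapping is deliberately
#' many-to-many: one enhancer may serve several genes and one gene several
#' enhancers. Chromosome names are matched as exact strings.
#'
#' @param peaks Peak `data.frame` from [read_peaks()].
#' @param genes Gene `data.frame` from [read_gene_annotation()].
#' @param window_bp Window in bp (default 1e6).
#' @return A `data.frame` with columns `peak_id`, `gene_id`, `distance_bp`,
#'   sorted by (`peak_id`, `distance_bp`, `gene_id`).
#' @export
link_peaks_to_genes <- function(peaks, genes, window_bp = 1000000L) {
  if (window_bp < 0) stop("window_bp must be >= 0")
  window_bp <- as.integer(window_bp)
  out <- list()
  for (chr in intersect(unique(peaks$chrom), unique(genes$chrom))) {
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    # peaks flanked by the window vs TSS points, both shifted to 1-based;
    # the downstream edge gains +1 because a TSS at 0-based position end+w
    # (gap exactly w past the half-open end) is still inside the window
    flanked <- IRanges::IRanges(start = p$start + 1L - window_bp,
                                end = p$end + window_bp + 1L)
    tss_pt <- IRanges::IRanges(start = g$tss + 1L, width = 1L)
    hits <- IRanges::findOverlaps(flanked, tss_pt)
    if (length(hits) == 0L) next
    pi <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    tss <- g$tss[gi]
    dist <- pmax(0L, pmax(p$start[pi] - tss, tss - p$end[pi]))
    out[[chr]] <- data.frame(peak_id = p$peak_id[pi], gene_id = g$gene_id[gi],
                             distance_bp = as.integer(dist),
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$peak_id, res$distance_bp, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Correlate linked peaks and genes across samples
#'
#' For each link, computes the correlation between the peak's normalized
#' signal row and the gene's FPKM row over a shared biological sample order
#' (each ChIP sample paired with the RNA sample from the same animal). A
#' zero-variance row leaves the link in place with missing r/p and
#' `correlated = FALSE`.
#'
#' @param links Link `data.frame` from [link_peaks_to_genes()].
#' @param chip_signal Numeric matrix (peaks x samples) from
#'   [normalize_peak_signal()].
#' @param expression Numeric matrix (genes x samples) from [compute_fpkm()].
#' @param sample_order Character vector of length >= 3 giving the shared
#'   biological sample order; must name columns of `chip_signal` and, via
#'   `rna_of`, of `expression`.
#' @param rna_of Optional named character vector mapping each entry of
#'   `sample_order` (a ChIP sample) to its RNA sample in `expression`;
#'   identity when omitted.
#' @param config [integration_config()] supplying `r_min`, `p_max`,
#'   `signed_r`.
#' @param method Correlation flavor, see [pearson_corr()].
#' @return `links` with `pearson_r`, `pearson_p`, `correlated` columns added.
#' @export
correlate_links <- function(links, chip_signal, expression, sample_order,
                            rna_of = NULL, config = integration_config(),
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(sample_order) < 3L) stop("correlation needs >= 3 shared samples")
  if (is.null(rna_of)) {
    rna_of <- stats::setNames(sample_order, sample_order)
  }
  if (any(!sample_order %in% colnames(chip_signal))) {
    stop("sample-order mismatch: sample(s) missing from chip signal matrix: ",
         paste(setdiff(sample_order, colnames(chip_signal)), collapse = ", "))
  }
  rna_samples <- unname(rna_of[sample_order])
  if (any(is.na(rna_samples)) || any(!rna_samples %in% colnames(expression))) {
    stop("sample-order mismatch: sample(s) missing from expression matrix")
  }
  sig <- chip_signal[, sample_order, drop = FALSE]
  expr <- expression[, rna_samples, drop = FALSE]
  missing_peak <- setdiff(unique(links$peak_id), rownames(sig))
  if (length(missing_peak)) {
    stop("link peak(s) missing from signal matrix: ",
         paste(utils::head(missing_peak, 5L), collapse = ", "))
  }
  missing_gene <- setdiff(unique(links$gene_id), rownames(expr))
  if (length(missing_gene)) {
    stop("link gene(s) missing from expression matrix: ",
         paste(utils::head(missing_gene, 5L), collapse = ", "))
  }
  n <- nrow(links)
  r <- rep(NA_real_, n); p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- sig[links$peak_id[i], ]
    y <- expr[links$gene_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    cc <- pearson_corr(x, y, method = method)
    r[i] <- cc$r; p[i] <- cc$p_value
  }
  links$pearson_r <- r
  links$pearson_p <- p
  rmag <- if (config$signed_r) r else abs(r)
  links$correlated <- !is.na(r) & rmag >= config$r_min & p < config$p_max
  links
}

#' Attach differential fold changes to links
#'
#' Joins the ChIP-side and RNA-side differential tables (from
#' [nb_differential()] on peak counts and gene counts) onto the link table.
#'
#' @param links Link `data.frame`.
#' @param chip_diff,rna_diff Differential `data.frame`s with `feature_id`,
#'   `log2fc` (and optionally `p_value`, `p_adj`).
#' @return `links` with `chip_log2fc`, `rna_log2fc` (and, when available,
#'   `chip_p`, `rna_p`) columns added.
#' @export
attach_fold_changes <- function(links, chip_diff, rna_diff) {
  pi <- match(links$peak_id, chip_diff$feature_id)
  gi <- match(links$gene_id, rna_diff$feature_id)
  if (any(is.na(pi))) {
    stop("link peak(s) missing from ChIP differential table: ",
         paste(utils::head(links$peak_id[is.na(pi)], 5L), collapse = ", "))
  }
  if (any(is.na(gi))) {
    stop("link gene(s) missing from RNA differential table: ",
         paste(utils::head(links$gene_id[is.na(gi)], 5L), collapse = ", "))
  }
  links$chip_log2fc <- chip_diff$log2fc[pi]
  links$rna_log2fc <- rna_diff$log2fc[gi]
  if ("p_value" %in% names(chip_diff)) links$chip_p <- chip_diff$p_value[pi]
  if ("p_value" %in% names(rna_diff)) links$rna_p <- rna_diff$p_value[gi]
  links
}

#' Classify linked pairs into fold-change quadrants
#'
#' Four-way genome-wide classification of linked peak-gene pairs by the signs
#' and magnitudes of their (ChIP, RNA) log2 fold changes, with strict
#' inequalities at the thresholds:
#' PP (chip > t_c and rna > t_r), NN (chip < -t_c and rna < -t_r),
#' PN (chip > t_c and rna < -t_r), NP (chip < -t_c and rna > t_r),
#' otherwise NS. The `correlated` flag is carried alongside rather than used
#' as a pre-filter, so both filtered and unfiltered tallies are reportable.
#'
#' @param links Link `data.frame` with `chip_log2fc` and `rna_log2fc`.
#' @param config [integration_config()] supplying the thresholds.
#' @return `links` with a `quadrant` factor-free character column added.
#' @export
classify_quadrants <- function(links, config = integration_config()) {
  if (!all(c("chip_log2fc", "rna_log2fc") %in% names(links))) {
    stop("links lack fold-change columns; run attach_fold_changes() first")
  }
  tc <- config$chip_lfc_min
  tr <- config$rna_lfc_min
  chip <- links$chip_log2fc
  rna <- links$rna_log2fc
  quadrant <- rep("NS", nrow(links))
  quadrant[chip > tc & rna > tr] <- "PP"
  quadrant[chip < -tc & rna < -tr] <- "NN"
  quadrant[chip > tc & rna < -tr] <- "PN"
  quadrant[chip < -tc & rna > tr] <- "NP"
  links$quadrant <- quadrant
  links
}

#' Tally links per quadrant
#'
#' @param links Classified link `data.frame` (with `quadrant`).
#' @param unique_genes Also report the number of distinct genes per quadrant
#'   (peaks and genes are not one-to-one).
#' @return A list with `counts` (named PP/NN/PN/NP), `total_classified`
#'   (their sum), `ns` and, optionally, `unique_genes`.
#' @export
quadrant_summary <- function(links, unique_genes = TRUE) {
  if (nrow(links) && !"quadrant" %in% names(links)) {
    stop("links lack a quadrant column; run classify_quadrants() first")
  }
  classes <- c("PP", "NN", "PN", "NP")
  counts <- vapply(classes, function(q) sum(links$quadrant == q), integer(1))
  res <- list(counts = counts,
              total_classified = sum(counts),
              ns = if (nrow(links)) sum(links$quadrant == "NS") else 0L)
  stopifnot(res$total_classified + res$ns == nrow(links))
  if (unique_genes) {
    res$unique_genes <- vapply(classes, function(q) {
      length(unique(links$gene_id[links$quadrant == q]))
    }, integer(1))
  }
  res
}

#' Rank the top peak-genes
#'
#' Among correlated PP/NN links, ranks by the product of fold-change
#' magnitudes `|chip_log2fc| * |rna_log2fc|` (descending), breaking ties by
#' larger `|pearson_r|`, then lexicographic (`peak_id`, `gene_id`), and
#' returns the top `k`.
#'
#' @param links Classified, correlated link `data.frame`.
#' @param k Number of links to return (> 0).
#' @return The top `k` (or fewer) links with a `score` column, rank order.
#' @export
rank_top_peak_genes <- function(links, k = 20L) {
  if (k <= 0) stop("k must be a positive integer")
  pool <- links[links$quadrant %in% c("PP", "NN") & links$correlated, ,
                drop = FALSE]
  if (nrow(pool) == 0L) {
    pool$score <- numeric(0)
    return(pool)
  }
  pool$score <- abs(pool$chip_log2fc) * abs(pool$rna_log2fc)
  ord <- order(-pool$score, -abs(pool$pearson_r), pool$peak_id, pool$gene_id)
  pool <- pool[ord, , drop = FALSE]
  rownames(pool) <- NULL
  utils::head(pool, k)
}
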
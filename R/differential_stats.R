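# Self-contained statistics: median-of-ratios size factors, a
# negative-binomial two-group Wald test (method-of-moments dispersion, no
# shrinkage), Benjamini-Hochberg adjustment, Pearson/Spearman correlation
# with p-values, and hypergeometric over-representation.

#' Median-of-ratios size factors
#'
#' Per sample, the median over features of `count(f, s) / reference(f)`,
#' where the reference is the per-feature geometric mean across samples,
#' computed over features with all-positive counts.
#'
#' @param counts Integer matrix (features x samples).
#' @param allow_pseudo_reference If `TRUE` and no feature has all-positive
#'   counts, fall back to a geometric mean over positive cells only.
#' @return A named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts, allow_pseudo_reference = FALSE) {
  if (ncol(counts) < 1L) stop("count matrix has no samples")
  all_pos <- rowSums(counts <= 0) == 0L
  if (!any(all_pos)) {
    if (!allow_pseudo_reference) {
      stop("no feature has all-positive counts; rerun with ",
           "allow_pseudo_reference = TRUE to use a pseudo-reference")
    }
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    ref <- exp(rowMeans(logc, na.rm = TRUE))
    keep <- is.finite(ref) & ref > 0
  } else {
    ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
    keep <- rep(TRUE, sum(all_pos))
    counts <- counts[all_pos, , drop = FALSE]
  }
  ratios <- counts[keep, , drop = FALSE] / ref[keep]
  sf <- apply(ratios, 2L, stats::median, na.rm = TRUE)
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("non-positive size factor estimated; counts too sparse")
  }
  sf
}

#' Negative-binomial two-group differential test
#'
#' Counts are divided by median-of-ratios size factors; the log2 fold change
#' (case over control) uses a pseudocount; the per-feature NB dispersion
#' alpha (variance mu + alpha mu^2) is estimated by method-of-moments on
#' normalized counts pooled within conditions and floored; the p-value is a
#' Wald-type normal approximation of the difference of log means with
#' delta-method NB variance. No dispersion shrinkage and no fold-change
#' shrinkage are applied.
#'
#' @param counts Integer matrix (features x samples).
#' @param samples Sample sheet restricted (by `assay`) to the samples in
#'   `counts`; must contain two conditions with >= 2 samples each.
#' @param pseudocount Added to both normalized group means in the fold change
#'   (default 0.5).
#' @param dispersion_floor Lower bound for alpha (default 1e-8) keeping the
#'   Poisson limit well defined.
#' @param sf Optional pre-computed size factors (named by sample).
#' @return A `data.frame` with one row per feature, in input order:
#'   `feature_id`, `base_mean`, `log2fc`, `p_value`, `p_adj` (BH).
#' @export
nb_differential <- function(counts, samples, pseudocount = 0.5,
                            dispersion_floor = 1e-8, sf = NULL) {
  samples <- validate_sample_sheet(samples)
  sid <- colnames(counts)
  idx <- match(sid, samples$sample_id)
  if (any(is.na(idx))) {
    stop("sample(s) missing from sample sheet: ",
         paste(sid[is.na(idx)], collapse = ", "))
  }
  cond <- samples$condition[idx]
  case <- sid[cond == "case"]
  ctrl <- sid[cond == "control"]
  if (length(case) < 2L || length(ctrl) < 2L) {
    stop("each condition needs >= 2 samples (got ", length(ctrl),
         " control, ", length(case), " case)")
  }
  if (is.null(sf)) {
    sf <- size_factors(counts, allow_pseudo_reference = TRUE)
  } else {
    sf <- sf[sid]
    if (any(is.na(sf))) stop("size factors missing for some samples")
  }
  norm <- sweep(counts, 2L, sf, `/`)
  x1 <- norm[, case, drop = FALSE]  # case
  x0 <- norm[, ctrl, drop = FALSE]  # control
  n1 <- length(case); n0 <- length(ctrl)
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  log2fc <- log2((mu1 + pseudocount) / (mu0 + pseudocount))
  # pooled within-condition method-of-moments dispersion:
  # alpha = (pooled var - pooled mean) / pooled mean^2
  v1 <- apply(x1, 1L, stats::var); v0 <- apply(x0, 1L, stats::var)
  pool_var <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / (n1 + n0 - 2L)
  pool_mu <- (n1 * mu1 + n0 * mu0) / (n1 + n0)
  alpha <- ifelse(pool_mu > 0, (pool_var - pool_mu) / pool_mu^2, 0)
  alpha <- pmax(alpha, dispersion_floor)
  # delta-method variance of log2((mu1 + pc)/(mu0 + pc))
  se2 <- ((mu1 + alpha * mu1^2) / (n1 * (mu1 + pseudocount)^2) +
          (mu0 + alpha * mu0^2) / (n0 * (mu0 + pseudocount)^2)) / log(2)^2
  z <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  zero <- mu1 == 0 & mu0 == 0
  log2fc[zero] <- 0
  p[zero] <- 1
  data.frame(feature_id = rownames(counts),
             base_mean = rowMeans(norm),
             log2fc = log2fc,
             p_value = p,
             p_adj = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, clipped to 1, in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Correlation between two sample vectors with a p-value
#'
#' Pearson (default) sample correlation with a two-sided p-value from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom;
#' `|r| = 1` gives p = 0. A Spearman option ranks both vectors first and
#' applies the same t approximation.
#'
#' @param x,y Numeric vectors of equal length n >= 3 with non-zero variance.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `p_value` and `n`.
#' @export
pearson_corr <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("correlation needs n >= 3 samples")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in correlation input")
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in input vector")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Hypergeometric over-representation of a query in a gene set
#'
#' Upper-tail hypergeometric test: the probability of drawing at least the
#' observed overlap when `query_size` genes are drawn without replacement
#' from a universe containing `set_size` annotated genes. Local stand-in for
#' web-based functional enrichment of PP/NN gene lists.
#'
#' @param query Character vector of query gene ids (must lie in `universe`).
#' @param gene_set Character vector of gene ids in the annotated set; only
#'   its intersection with `universe` is used.
#' @param universe Character vector of all testable gene ids.
#' @param set_name Optional label for the result row.
#' @return A one-row `data.frame`: `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value` (`p_adj` is filled with
#'   `p_value`; use [bh_adjust()] across sets).
#' @export
hypergeom_enrich <- function(query, gene_set, universe, set_name = "set") {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query gene(s) outside universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  set_in <- intersect(unique(gene_set), universe)
  overlap <- length(intersect(query, set_in))
  m <- length(set_in)              # annotated
  n <- length(universe) - m        # not annotated
  k <- length(query)               # drawn
  p <- if (k == 0L || m == 0L) {
    if (overlap == 0L) 1 else 0    # overlap > 0 impossible here
  } else {
    stats::phyper(overlap - 1L, m, n, k, lower.tail = FALSE)
  }
  data.frame(set_name = set_name, overlap = overlap, set_size = m,
             query_size = k, universe_size = length(universe),
             p_value = p, p_adj = p, stringsAsFactors = FALSE)
}

#' Enrichment of a query list against a GMT collection
#'
#' Applies [hypergeom_enrich()] to every set in a GMT collection and adjusts
#' the p-values across sets with Benjamini-Hochberg.
#'
#' @param query Character vector of query gene ids.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Character vector of all testable gene ids.
#' @return A `data.frame` with one row per set, ordered by `p_value`.
#' @export
enrich_gene_sets <- function(query, gene_sets, universe) {
  rows <- mapply(function(set, nm) {
    hypergeom_enrich(query, set, universe, set_name = nm)
  }, gene_sets, names(gene_sets), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}
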
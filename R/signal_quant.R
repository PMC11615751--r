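# Normalization of raw counts into per-peak acetylation signal and per-gene
# FPKM. Two-track design: the differential test (differential_stats) works on
# raw counts with size factors; the correlation stage works on the normalized,
# input-subtracted signal produced here.

#' Compute FPKM from a gene count matrix
#'
#' FPKM(g, s) = count(g, s) * 1e9 / (gene_length(g) * library_size(s)),
#' i.e. fragments per kilobase of transcript per million mapped fragments.
#' Library sizes come from the sample sheet, not from column sums.
#'
#' @param gene_counts Integer matrix (genes x samples) as from
#'   [read_count_matrix()].
#' @param genes Gene annotation `data.frame` with `gene_id` and `gene_length`.
#' @param samples Sample sheet `data.frame` (see [read_sample_sheet()]).
#' @return A numeric matrix of FPKM values, same dimnames as `gene_counts`.
#' @export
compute_fpkm <- function(gene_counts, genes, samples) {
  samples <- validate_sample_sheet(samples)
  gid <- rownames(gene_counts)
  sid <- colnames(gene_counts)
  idx <- match(gid, genes$gene_id)
  if (any(is.na(idx))) {
    stop("gene(s) in count matrix missing from annotation: ",
         paste(utils::head(gid[is.na(idx)], 5L), collapse = ", "))
  }
  len <- genes$gene_length[idx]
  if (any(!is.finite(len)) || any(len < 1)) {
    stop("missing or invalid gene_length for: ",
         paste(utils::head(gid[!is.finite(len) | len < 1], 5L),
               collapse = ", "))
  }
  sidx <- match(sid, samples$sample_id)
  if (any(is.na(sidx))) {
    stop("sample(s) in count matrix missing from sample sheet: ",
         paste(sid[is.na(sidx)], collapse = ", "))
  }
  lib <- samples$library_size[sidx]
  fpkm <- sweep(gene_counts * 1e9 / len, 2L, lib, `/`)
  dimnames(fpkm) <- dimnames(gene_counts)
  fpkm
}

#' Estimate background scale factors from genomic bins
#'
#' For each ChIP/input sample pair, compares depth-normalized coverage over
#' small genomic bins (default 20 bp bins tiling ~1 Mb of mappable sequence,
#' outside peaks) and returns the median per-bin ratio
#' `(chip/N_chip) / (input/N_input)` over bins with non-zero input. This
#' factor rescales input before subtraction so that background regions
#' cancel even when ChIP and input differ in global enrichment.
#'
#' @param chip_bins,input_bins Integer matrices (bins x samples) with
#'   identical bin feature ids.
#' @param samples Sample sheet providing `library_size`.
#' @param pairing Named character vector mapping each ChIP `sample_id` to its
#'   input `sample_id`.
#' @param method `"median"` (robust default) or `"mean"` of per-bin ratios.
#' @param bin_width,region_span Recorded metadata (base pairs).
#' @return A `data.frame` with one row per ChIP sample: `sample_id`,
#'   `input_sample_id`, `scale_factor`, `n_bins_used`, `bin_width`,
#'   `region_span`.
#' @export
estimate_background_scale <- function(chip_bins, input_bins, samples, pairing,
                                      method = c("median", "mean"),
                                      bin_width = 20L,
                                      region_span = 1000000L) {
  method <- match.arg(method)
  samples <- validate_sample_sheet(samples)
  if (!identical(rownames(chip_bins), rownames(input_bins))) {
    stop("chip and input bin matrices must share identical bin features")
  }
  chip_ids <- names(pairing)
  if (any(!chip_ids %in% colnames(chip_bins))) {
    stop("paired ChIP sample(s) missing from chip bin matrix")
  }
  if (any(!pairing %in% colnames(input_bins))) {
    stop("paired input sample(s) missing from input bin matrix")
  }
  res <- lapply(chip_ids, function(s) {
    t <- pairing[[s]]
    n_s <- samples$library_size[match(s, samples$sample_id)]
    n_t <- samples$library_size[match(t, samples$sample_id)]
    if (is.na(n_s) || is.na(n_t)) {
      stop("sample missing from sample sheet: ",
           paste(c(s, t)[is.na(c(n_s, n_t))], collapse = ", "))
    }
    use <- input_bins[, t] > 0
    if (!any(use)) stop("no background bin with input > 0 for pair ", s,
                        " / ", t)
    ratio <- (chip_bins[use, s] / n_s) / (input_bins[use, t] / n_t)
    sf <- if (method == "median") stats::median(ratio) else mean(ratio)
    data.frame(sample_id = s, input_sample_id = t, scale_factor = sf,
               n_bins_used = sum(use), bin_width = bin_width,
               region_span = region_span, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Normalize per-peak ChIP signal with input subtraction
#'
#' Converts raw ChIP and input counts over peaks into input-subtracted signal
#' densities. Per peak p, ChIP sample s with paired input t:
#' \deqn{dens_{chip} = c(p,s) K / (N_s L_p), \quad
#'       dens_{input} = i(p,t) K / (N_t L_p)}
#' \deqn{signal = \max(0,\ dens_{chip} - \beta\, dens_{input})}
#' with K = 1e9 (reads-per-kilobase-per-million style constant; any common
#' constant cancels in fold changes), L_p the peak length, N the library size
#' from the sample sheet, and beta the background scale factor (1 when no
#' background estimate is supplied). Negative post-subtraction values are
#' floored at 0: negative acetylation density is meaningless and would break
#' downstream log fold changes.
#'
#' @param chip,input Integer matrices (peaks x samples) sharing feature ids.
#' @param peaks Peak `data.frame` from [read_peaks()].
#' @param samples Sample sheet providing `library_size`.
#' @param pairing Named character vector mapping each ChIP `sample_id` in
#'   `chip` to its input `sample_id` in `input`.
#' @param background Optional `data.frame` from [estimate_background_scale()];
#'   its `scale_factor` per ChIP sample is used as beta.
#' @param scale_constant The constant K (default 1e9).
#' @return A numeric matrix (peaks x ChIP samples) of non-negative signal,
#'   with a `normalization_meta` attribute recording K, the library sizes and
#'   the beta used per sample.
#' @export
normalize_peak_signal <- function(chip, input, peaks, samples, pairing,
                                  background = NULL, scale_constant = 1e9) {
  samples <- validate_sample_sheet(samples)
  if (!identical(rownames(chip), rownames(input))) {
    stop("chip and input matrices must share identical peak feature ids")
  }
  pidx <- match(rownames(chip), peaks$peak_id)
  if (any(is.na(pidx))) {
    stop("peak(s) in count matrix missing from peak list: ",
         paste(utils::head(rownames(chip)[is.na(pidx)], 5L), collapse = ", "))
  }
  len <- (peaks$end - peaks$start)[pidx]
  chip_ids <- colnames(chip)
  if (any(!chip_ids %in% names(pairing))) {
    stop("unpaired ChIP sample(s): ",
         paste(setdiff(chip_ids, names(pairing)), collapse = ", "))
  }
  beta <- stats::setNames(rep(1, length(chip_ids)), chip_ids)
  if (!is.null(background)) {
    bidx <- match(chip_ids, background$sample_id)
    beta[!is.na(bidx)] <- background$scale_factor[bidx[!is.na(bidx)]]
  }
  if (any(beta <= 0)) stop("background scale_factor must be positive")
  signal <- matrix(0, nrow = nrow(chip), ncol = length(chip_ids),
                   dimnames = list(rownames(chip), chip_ids))
  meta_lib <- list()
  for (s in chip_ids) {
    t <- pairing[[s]]
    if (!t %in% colnames(input)) {
      stop("paired input sample '", t, "' missing from input matrix")
    }
    n_s <- samples$library_size[match(s, samples$sample_id)]
    n_t <- samples$library_size[match(t, samples$sample_id)]
    if (is.na(n_s) || is.na(n_t)) {
      stop("sample missing from sample sheet: ",
           paste(c(s, t)[is.na(c(n_s, n_t))], collapse = ", "))
    }
    dens_chip <- chip[, s] * scale_constant / (n_s * len)
    dens_input <- input[, t] * scale_constant / (n_t * len)
    signal[, s] <- pmax(0, dens_chip - beta[[s]] * dens_input)
    meta_lib[[s]] <- c(chip_library = n_s, input_library = n_t,
                       beta = unname(beta[[s]]))
  }
  attr(signal, "normalization_meta") <-
    list(scale_constant = scale_constant, pairing = pairing,
         per_sample = meta_lib)
  signal
}

#' Per-base coverage sums over intervals from a BAM file (bedcov semantics)
#'
#' For each interval, sums the per-base read depth across the interval, as
#' `samtools bedcov` does. Optional acquisition path: the rest of the
#' pipeline consumes count matrices and never requires BAM input.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM file.
#' @param intervals Peak `data.frame` from [read_peaks()] (0-based half-open
#'   coordinates).
#' @return An integer vector of coverage sums, named by `peak_id`, usable as
#'   one sample column of a count matrix.
#' @export
quantify_bam_over_intervals <- function(bam_path, intervals) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("quantify_bam_over_intervals requires the Rsamtools package")
  }
  if (!file.exists(bam_path)) stop("BAM file does not exist: ", bam_path)
  bai <- paste0(bam_path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    stop("BAM index (.bai) not found for ", bam_path)
  }
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  missing_contig <- setdiff(unique(intervals$chrom), names(hdr))
  if (length(missing_contig)) {
    stop("contig(s) absent from BAM header: ",
         paste(missing_contig, collapse = ", "))
  }
  which <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  param <- Rsamtools::ScanBamParam(which = which)
  pp <- Rsamtools::PileupParam(max_depth = 1e6L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = FALSE)
  pile <- Rsamtools::pileup(bam_path, scanBamParam = param, pileupParam = pp)
  # pileup labels each position with the query range it fell in
  out <- stats::setNames(integer(nrow(intervals)), intervals$peak_id)
  if (nrow(pile)) {
    sums <- tapply(pile$count, pile$which_label, sum)
    sums <- sums[!is.na(sums)]   # drop unused which_label factor levels
    labels <- sprintf("%s:%d-%d", intervals$chrom, intervals$start + 1L,
                      intervals$end)
    hit <- match(names(sums), labels)
    out[hit[!is.na(hit)]] <- as.integer(sums[!is.na(hit)])
  }
  out
}
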
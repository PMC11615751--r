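# Coupled ChIP/input/RNA count simulator with planted PP/NN/PN/NP peak-gene
# structure, standing in for the unavailable rat sequencing data. Every draw
# is governed by the config seed, so a config determines its dataset exactly.

#' Simulation configuration
#'
#' Describes the simulated two-condition experiment: 3 biological replicates
#' per condition by default (the sequenced design), negative-binomial counts
#' with variance mu + alpha mu^2, planted condition effects on the log2
#' scale chosen to straddle the classification thresholds (ChIP 2.0 vs
#' threshold 1; RNA 6.0 vs threshold 5), and replicate-level coupling between
#' a peak and its partner gene through a shared per-sample latent factor.
#'
#' @param seed Integer seed; fully determines the dataset.
#' @param n_per_group Biological replicates per condition (default 3).
#' @param n_genes,n_peaks Feature counts (defaults 2000 each). The first
#'   `min(n_peaks, n_genes)` peak/gene indices form planted pairs.
#' @param frac_pp,frac_nn,frac_pn,frac_np Fractions of planted pairs assigned
#'   to each coupled class (defaults 0.025 each, i.e. 50 pairs per class and
#'   200 coupled pairs at the default size, keeping the differential fraction
#'   near the ~10 percent a real two-condition experiment shows; the
#'   remainder are planted null pairs: linked in space, no effect, no latent
#'   coupling).
#' @param chip_effect_log2,rna_effect_log2 Case-vs-control condition effects
#'   (log2) applied per class sign pattern (defaults 2.0 and 6.0).
#' @param nb_dispersion NB dispersion alpha (default 0.1).
#' @param base_mean_chip,base_mean_rna Baseline NB means (defaults 100, 200).
#' @param feature_sd_log2 SD of per-feature baseline variation on the log2
#'   scale (default 0.5).
#' @param latent_sd_log2 SD (log2) of the shared per-sample latent factor
#'   that couples a peak with its partner gene (default 0.3).
#' @param chip_to_input_enrichment ChIP-over-input mean ratio at peaks
#'   (default 3), so input subtraction is exercised nontrivially.
#' @param genome Data frame with `chrom`, `length`; default 20 chromosomes of
#'   150 Mb (a rat-scale 3 Gb genome, keeping incidental peak-gene adjacency
#'   rare) plus a dedicated background contig tiled by the bins.
#' @param window_bp Linking window the planted pairs are placed within
#'   (default 1e6).
#' @param n_background_bins,bin_width Background bins (defaults 50000 bins of
#'   20 bp, i.e. 1 Mb of background sequence).
#' @param bin_mean NB mean of background-bin input coverage (default 5).
#' @param library_size_chip,library_size_rna Declared total mapped reads per
#'   library (defaults 2e7 and 3e7).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_per_group = 3L, n_genes = 2000L,
                              n_peaks = 2000L, frac_pp = 0.025,
                              frac_nn = 0.025, frac_pn = 0.025,
                              frac_np = 0.025,
                              chip_effect_log2 = 2.0, rna_effect_log2 = 6.0,
                              nb_dispersion = 0.1, base_mean_chip = 100,
                              base_mean_rna = 200, feature_sd_log2 = 0.5,
                              latent_sd_log2 = 0.3,
                              chip_to_input_enrichment = 3,
                              genome = NULL, window_bp = 1000000L,
                              n_background_bins = 50000L, bin_width = 20L,
                              bin_mean = 5, library_size_chip = 2e7,
                              library_size_rna = 3e7) {
  fracs <- c(frac_pp, frac_nn, frac_pn, frac_np)
  stopifnot(all(fracs >= 0), sum(fracs) <= 1, n_per_group >= 2,
            n_genes >= 1, n_peaks >= 1, nb_dispersion >= 0,
            window_bp > 0, n_background_bins >= 1, bin_width >= 1)
  if (is.null(genome)) {
    genome <- data.frame(
      chrom = c(paste0("chr", 1:20), "chrBG"),
      length = c(rep(150000000L, 20L),
                 as.integer(n_background_bins) * as.integer(bin_width)),
      stringsAsFactors = FALSE)
  }
  structure(list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
                 n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
                 frac_pp = frac_pp, frac_nn = frac_nn, frac_pn = frac_pn,
                 frac_np = frac_np, chip_effect_log2 = chip_effect_log2,
                 rna_effect_log2 = rna_effect_log2,
                 nb_dispersion = nb_dispersion,
                 base_mean_chip = base_mean_chip,
                 base_mean_rna = base_mean_rna,
                 feature_sd_log2 = feature_sd_log2,
                 latent_sd_log2 = latent_sd_log2,
                 chip_to_input_enrichment = chip_to_input_enrichment,
                 genome = genome, window_bp = as.integer(window_bp),
                 n_background_bins = as.integer(n_background_bins),
                 bin_width = as.integer(bin_width), bin_mean = bin_mean,
                 library_size_chip = library_size_chip,
                 library_size_rna = library_size_rna),
            class = "simulation_config")
}

# NB draws parameterized by mean and dispersion alpha (variance mu+alpha mu^2)
.rnb <- function(n, mu, alpha) {
  if (alpha <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate a coupled ChIP/input/RNA dataset with planted peak-gene classes
#'
#' Places gene TSSs uniformly on the simulated genome (background contig
#' excluded), places each planted pair's peak within the linking window of
#' its partner gene's TSS, and draws NB counts: ChIP and RNA counts carry the
#' class-specific condition effects (PP: +chip,+rna; NN: -,-; PN: +,-;
#' NP: -,+) and, for coupled (non-null) pairs, a shared per-sample log-normal
#' latent factor that induces replicate-level cross-correlation (inverted on
#' the RNA side for PN/NP, so their expected correlation is negative). Input
#' and background-bin counts carry no condition effect. Deterministic under
#' the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `peaks`, `genes` (annotation tables),
#'   `chip_counts`, `input_counts`, `chip_bins`, `input_bins`, `gene_counts`
#'   (integer matrices), `samples` (sample sheet), `pairing` (chip -> input),
#'   `rna_of` (chip -> rna, same animal), `truth` (planted pair table with
#'   `peak_id`, `gene_id`, `class`, `chip_effect_log2`, `rna_effect_log2`,
#'   `distance_bp`) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  genome <- config$genome[config$genome$chrom != "chrBG", , drop = FALSE]
  margin <- config$window_bp + 2000000L
  if (any(genome$length < 2 * margin)) {
    stop("genome too small to place features: chromosomes must exceed ",
         2 * margin, " bp")
  }

  ## --- sample sheet -------------------------------------------------------
  conditions <- rep(c("control", "case"), each = n)
  rep_id <- rep(seq_len(n), 2L)
  chip_ids <- sprintf("chip_%s_%d", conditions, rep_id)
  input_ids <- sprintf("input_%s_%d", conditions, rep_id)
  rna_ids <- sprintf("rna_%s_%d", conditions, rep_id)
  samples <- data.frame(
    sample_id = c(chip_ids, input_ids, rna_ids),
    condition = rep(conditions, 3L),
    assay = rep(c("chip", "input", "rna"), each = 2L * n),
    library_size = c(rep(config$library_size_chip, 4L * n),
                     rep(config$library_size_rna, 2L * n)),
    stringsAsFactors = FALSE)
  pairing <- stats::setNames(input_ids, chip_ids)
  rna_of <- stats::setNames(rna_ids, chip_ids)
  is_case <- conditions == "case"

  ## --- planted pair classes ----------------------------------------------
  n_pairs <- min(config$n_peaks, config$n_genes)
  n_class <- c(PP = floor(config$frac_pp * n_pairs),
               NN = floor(config$frac_nn * n_pairs),
               PN = floor(config$frac_pn * n_pairs),
               NP = floor(config$frac_np * n_pairs))
  classes <- c(rep(names(n_class), n_class),
               rep("null", n_pairs - sum(n_class)))
  sign_map <- list(PP = c(1, 1), NN = c(-1, -1), PN = c(1, -1),
                   NP = c(-1, 1), null = c(0, 0))

  ## --- genomic placement --------------------------------------------------
  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  peak_ids <- sprintf("peak_%04d", seq_len(config$n_peaks))
  g_chr <- sample(genome$chrom, config$n_genes, replace = TRUE,
                  prob = genome$length)
  g_tss <- vapply(g_chr, function(ch) {
    L <- genome$length[genome$chrom == ch]
    as.integer(floor(stats::runif(1, margin, L - margin)))
  }, integer(1))
  g_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  g_len <- as.integer(floor(stats::runif(config$n_genes, 1000, 20000)))
  g_start <- ifelse(g_strand == "+", g_tss, g_tss - g_len + 1L)
  g_end <- g_start + g_len
  genes <- data.frame(gene_id = gene_ids, chrom = unname(g_chr),
                      start = as.integer(g_start), end = as.integer(g_end),
                      strand = g_strand, tss = g_tss, gene_length = g_len,
                      stringsAsFactors = FALSE)

  p_width <- as.integer(floor(stats::runif(config$n_peaks, 400, 2000)))
  p_chr <- character(config$n_peaks)
  p_start <- integer(config$n_peaks)
  pair_dist <- integer(n_pairs)
  for (i in seq_len(config$n_peaks)) {
    if (i <= n_pairs) {
      # place within the window of partner gene i's TSS
      d <- as.integer(floor(stats::runif(1, 0, 0.8 * config$window_bp)))
      side <- sample(c(-1L, 1L), 1L)
      p_chr[i] <- genes$chrom[i]
      p_start[i] <- if (side > 0L) genes$tss[i] + d
                    else genes$tss[i] - d - p_width[i]
      pair_dist[i] <- d
    } else {
      ch <- sample(genome$chrom, 1L, prob = genome$length)
      L <- genome$length[genome$chrom == ch]
      p_chr[i] <- ch
      p_start[i] <- as.integer(floor(stats::runif(1, margin, L - margin)))
    }
  }
  peaks <- data.frame(peak_id = peak_ids, chrom = p_chr, start = p_start,
                      end = p_start + p_width,
                      source_line = seq_len(config$n_peaks),
                      stringsAsFactors = FALSE)

  ## --- per-feature baselines and condition effects ------------------------
  chip_base <- config$base_mean_chip *
    2^stats::rnorm(config$n_peaks, 0, config$feature_sd_log2)
  rna_base <- config$base_mean_rna *
    2^stats::rnorm(config$n_genes, 0, config$feature_sd_log2)
  chip_eff <- numeric(config$n_peaks)   # log2 case-vs-control, per peak
  rna_eff <- numeric(config$n_genes)
  rna_latent_sign <- numeric(config$n_genes)  # 0 = uncoupled
  chip_latent <- logical(config$n_peaks)
  for (j in seq_len(n_pairs)) {
    s <- sign_map[[classes[j]]]
    chip_eff[j] <- s[1] * config$chip_effect_log2
    rna_eff[j] <- s[2] * config$rna_effect_log2
    if (classes[j] != "null") {
      chip_latent[j] <- TRUE
      rna_latent_sign[j] <- if (classes[j] %in% c("PP", "NN")) 1 else -1
    }
  }

  ## --- count draws ---------------------------------------------------------
  alpha <- config$nb_dispersion
  n_samp <- 2L * n
  # shared latent factor per planted pair and biological replicate
  latent <- matrix(stats::rnorm(n_pairs * n_samp, 0, config$latent_sd_log2),
                   nrow = n_pairs)
  chip_mu <- matrix(rep(chip_base, n_samp), ncol = n_samp)
  chip_mu[, is_case] <- chip_mu[, is_case] * 2^chip_eff
  gene_mu <- matrix(rep(rna_base, n_samp), ncol = n_samp)
  gene_mu[, is_case] <- gene_mu[, is_case] * 2^rna_eff
  if (n_pairs > 0) {
    coup <- which(chip_latent)
    chip_mu[coup, ] <- chip_mu[coup, , drop = FALSE] *
      2^latent[coup, , drop = FALSE]
    gene_mu[coup, ] <- gene_mu[coup, , drop = FALSE] *
      2^(latent[coup, , drop = FALSE] * rna_latent_sign[coup])
  }
  input_mu <- matrix(rep(chip_base / config$chip_to_input_enrichment, n_samp),
                     ncol = n_samp)

  draw <- function(mu) {
    m <- matrix(.rnb(length(mu), as.vector(mu), alpha), nrow = nrow(mu))
    storage.mode(m) <- "integer"
    m
  }
  chip_counts <- draw(chip_mu)
  dimnames(chip_counts) <- list(peak_ids, chip_ids)
  input_counts <- draw(input_mu)
  dimnames(input_counts) <- list(peak_ids, input_ids)
  gene_counts <- draw(gene_mu)
  dimnames(gene_counts) <- list(gene_ids, rna_ids)

  nb <- config$n_background_bins
  bin_ids <- sprintf("bin_%06d", seq_len(nb))
  bin_mu <- matrix(config$bin_mean, nrow = nb, ncol = n_samp)
  chip_bins <- draw(bin_mu)
  dimnames(chip_bins) <- list(bin_ids, chip_ids)
  input_bins <- draw(bin_mu)
  dimnames(input_bins) <- list(bin_ids, input_ids)
  attr(chip_counts, "feature_kind") <- "peak"
  attr(input_counts, "feature_kind") <- "peak"
  attr(gene_counts, "feature_kind") <- "gene"
  attr(chip_bins, "feature_kind") <- "bin"
  attr(input_bins, "feature_kind") <- "bin"

  truth <- data.frame(peak_id = peak_ids[seq_len(n_pairs)],
                      gene_id = gene_ids[seq_len(n_pairs)],
                      class = classes,
                      chip_effect_log2 = chip_eff[seq_len(n_pairs)],
                      rna_effect_log2 = rna_eff[seq_len(n_pairs)],
                      distance_bp = pair_dist,
                      stringsAsFactors = FALSE)

  list(peaks = peaks, genes = genes, chip_counts = chip_counts,
       input_counts = input_counts, chip_bins = chip_bins,
       input_bins = input_bins, gene_counts = gene_counts,
       samples = samples, pairing = pairing, rna_of = rna_of,
       truth = truth, config = config)
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' BED peaks, GTF gene annotation, TSV count matrices, TSV sample sheet and
#' a TSV truth table, as the file-based pipeline entry points expect.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_peaks(sim$peaks, file.path(dir, "peaks.bed"))
  write_gene_annotation(sim$genes, file.path(dir, "genes.gtf"))
  write_count_matrix(sim$chip_counts, file.path(dir, "chip_counts.tsv"))
  write_count_matrix(sim$input_counts, file.path(dir, "input_counts.tsv"))
  write_count_matrix(sim$chip_bins, file.path(dir, "chip_bins.tsv"))
  write_count_matrix(sim$input_bins, file.path(dir, "input_bins.tsv"))
  write_count_matrix(sim$gene_counts, file.path(dir, "gene_counts.tsv"))
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chip = names(sim$pairing), input = unname(sim$pairing),
               rna = unname(sim$rna_of)),
    file.path(dir, "pairing.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Score recovery of planted peak-gene classes
#'
#' Compares the classified link table against the planted truth. A planted
#' pair absent from the links counts as unrecovered. Links not present in
#' the truth (incidental spatial links between unrelated features) are
#' tallied separately and do not enter recall or precision.
#'
#' @param truth Truth table from [simulate_dataset()].
#' @param links Classified link `data.frame` (with `quadrant`).
#' @return A list: `recall` and `precision` (named per class PP/NN/PN/NP),
#'   `null_false_rate` (planted null pairs classified non-NS),
#'   `confusion` (planted class x assigned label table),
#'   `n_incidental_links`.
#' @export
evaluate_recovery <- function(truth, links) {
  if (nrow(links) && !"quadrant" %in% names(links)) {
    stop("links lack a quadrant column; run classify_quadrants() first")
  }
  key_t <- paste(truth$peak_id, truth$gene_id, sep = "\r")
  key_l <- paste(links$peak_id, links$gene_id, sep = "\r")
  if (anyDuplicated(key_t)) stop("duplicate pair in truth table")
  idx <- match(key_t, key_l)
  assigned <- ifelse(is.na(idx), "unlinked", links$quadrant[idx])
  classes <- c("PP", "NN", "PN", "NP")
  recall <- vapply(classes, function(cl) {
    planted <- truth$class == cl
    if (!any(planted)) return(NA_real_)
    mean(assigned[planted] == cl)
  }, numeric(1))
  precision <- vapply(classes, function(cl) {
    called <- assigned == cl
    if (!any(called)) return(NA_real_)
    mean(truth$class[called] == cl)
  }, numeric(1))
  nulls <- truth$class == "null"
  null_false_rate <- if (any(nulls)) {
    mean(assigned[nulls] %in% classes)
  } else NA_real_
  confusion <- table(planted = factor(truth$class,
                                      levels = c(classes, "null")),
                     assigned = factor(assigned,
                                       levels = c(classes, "NS", "unlinked")))
  list(recall = recall, precision = precision,
       null_false_rate = null_false_rate, confusion = confusion,
       n_incidental_links = sum(!key_l %in% key_t))
}
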
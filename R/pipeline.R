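# Orchestration: one call (or one CLI invocation) that runs the whole
# integrative analysis — simulate (optionally), quantify, differential test
# on both assays, link, correlate, classify, summarize, rank, score recovery
# — writing every stage's output plus a machine-readable run manifest.

#' Run the full integrative pipeline
#'
#' Executes the stage sequence on either a simulated dataset (when
#' `sim_config` is given) or a pre-loaded dataset (`data`, shaped like the
#' return value of [simulate_dataset()]; `truth` may be absent). Stage
#' outputs are pure functions of (inputs, config, seed): two runs with
#' identical inputs produce identical outputs.
#'
#' @param sim_config Optional [simulation_config()]; when given, the dataset
#'   is simulated first.
#' @param data Optional pre-loaded dataset list with elements `peaks`,
#'   `genes`, `chip_counts`, `input_counts`, `gene_counts`, `samples`,
#'   `pairing`, `rna_of`, and optionally `chip_bins`/`input_bins` and
#'   `truth`. Ignored when `sim_config` is given.
#' @param config [integration_config()] with the linking/correlation/
#'   classification thresholds.
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written there (integration TSV, differential TSVs, summary and manifest
#'   JSON).
#' @param top_k Number of top peak-genes to rank (default 20).
#' @param use_background If `TRUE` (default) and bin matrices are present,
#'   estimate background scale factors and use them in input subtraction.
#' @return A list: `links` (classified integration table), `chip_diff`,
#'   `rna_diff`, `signal`, `fpkm`, `summary` (quadrant tallies), `top`
#'   (ranked links), `background`, `recovery` (when truth available),
#'   `manifest`.
#' @export
run_pipeline <- function(sim_config = NULL, data = NULL,
                         config = integration_config(), out_dir = NULL,
                         top_k = 20L, use_background = TRUE) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  if (!is.null(sim_config)) {
    data <- simulate_dataset(sim_config)
    tick("simulate")
  }
  if (is.null(data)) stop("either sim_config or data must be supplied")
  for (el in c("peaks", "genes", "chip_counts", "input_counts",
               "gene_counts", "samples", "pairing", "rna_of")) {
    if (is.null(data[[el]])) stop("pipeline input lacks element '", el, "'")
  }
  samples <- validate_sample_sheet(data$samples)

  background <- NULL
  if (use_background && !is.null(data$chip_bins) &&
      !is.null(data$input_bins)) {
    background <- estimate_background_scale(data$chip_bins, data$input_bins,
                                            samples, data$pairing)
    tick("background")
  }
  signal <- normalize_peak_signal(data$chip_counts, data$input_counts,
                                  data$peaks, samples, data$pairing,
                                  background = background)
  fpkm <- compute_fpkm(data$gene_counts, data$genes, samples)
  tick("quantify")

  chip_diff <- nb_differential(data$chip_counts, samples)
  rna_diff <- nb_differential(data$gene_counts, samples)
  tick("differential")

  links <- link_peaks_to_genes(data$peaks, data$genes, config$window_bp)
  tick("link")
  chip_order <- colnames(data$chip_counts)
  links <- correlate_links(links, signal, fpkm, chip_order,
                           rna_of = data$rna_of, config = config)
  tick("correlate")
  links <- attach_fold_changes(links, chip_diff, rna_diff)
  links <- classify_quadrants(links, config)
  summary <- quadrant_summary(links)
  top <- rank_top_peak_genes(links, k = top_k)
  tick("classify")

  recovery <- NULL
  if (!is.null(data$truth)) {
    recovery <- evaluate_recovery(data$truth, links)
    tick("recovery")
  }

  manifest <- list(
    thresholds = unclass(config),
    seed = if (!is.null(sim_config)) sim_config$seed else NA,
    n_peaks = nrow(data$peaks), n_genes = nrow(data$genes),
    n_samples = nrow(samples),
    n_links = nrow(links),
    quadrant_counts = as.list(summary$counts),
    total_classified = summary$total_classified,
    normalization = list(
      scale_constant = attr(signal, "normalization_meta")$scale_constant,
      background_used = !is.null(background)),
    timings_sec = timings)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_integration_table(links, file.path(out_dir, "integration.tsv"))
    utils::write.table(chip_diff, file.path(out_dir, "chip_differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rna_diff, file.path(out_dir, "rna_differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(top)) {
      write_integration_table(top[, setdiff(names(top), "score")],
                              file.path(out_dir, "top_peak_genes.tsv"))
    }
    jsonlite::write_json(
      list(counts = as.list(summary$counts),
           total_classified = summary$total_classified, ns = summary$ns,
           unique_genes = as.list(summary$unique_genes)),
      file.path(out_dir, "quadrant_summary.json"), auto_unbox = TRUE)
    if (!is.null(recovery)) {
      jsonlite::write_json(
        list(recall = as.list(recovery$recall),
             precision = as.list(recovery$precision),
             null_false_rate = recovery$null_false_rate,
             n_incidental_links = recovery$n_incidental_links),
        file.path(out_dir, "recovery.json"), auto_unbox = TRUE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(links = links, chip_diff = chip_diff, rna_diff = rna_diff,
       signal = signal, fpkm = fpkm, summary = summary, top = top,
       background = background, recovery = recovery, manifest = manifest)
}

#' Load a file-based dataset for [run_pipeline()]
#'
#' Reads the plain-text layout written by [write_simulation()] (or prepared
#' by hand from real data): `peaks.bed`, `genes.gtf`, the count TSVs,
#' `samples.tsv`, `pairing.tsv` and, when present, `truth.tsv`.
#'
#' @param dir Directory containing the files.
#' @return A dataset list suitable for `run_pipeline(data = ...)`.
#' @export
read_dataset <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("dataset file missing: ", p)
    p
  }
  pairing_tab <- utils::read.table(need("pairing.tsv"), sep = "\t",
                                   header = TRUE, stringsAsFactors = FALSE)
  data <- list(
    peaks = read_peaks(need("peaks.bed")),
    genes = read_gene_annotation(need("genes.gtf"), format = "gtf"),
    chip_counts = read_count_matrix(need("chip_counts.tsv"), "peak"),
    input_counts = read_count_matrix(need("input_counts.tsv"), "peak"),
    gene_counts = read_count_matrix(need("gene_counts.tsv"), "gene"),
    samples = read_sample_sheet(need("samples.tsv")),
    pairing = stats::setNames(pairing_tab$input, pairing_tab$chip),
    rna_of = stats::setNames(pairing_tab$rna, pairing_tab$chip))
  for (f in c("chip_bins", "input_bins")) {
    p <- file.path(dir, paste0(f, ".tsv"))
    if (file.exists(p)) data[[f]] <- read_count_matrix(p, "bin")
  }
  tp <- file.path(dir, "truth.tsv")
  if (file.exists(tp)) {
    data$truth <- utils::read.table(tp, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
  }
  data
}
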
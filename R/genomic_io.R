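# Readers/writers for the genomic and tabular formats the pipeline touches.
# One internal coordinate convention everywhere: 0-based, half-open, as in BED.
# GTF (1-based, inclusive) is converted at the boundary and nowhere else.

#' Read peak intervals from a BED or narrowPeak file
#'
#' Parses the first three (coordinates) and optional fourth (name) columns of
#' a BED-family file into a peak table. Coordinates are kept in the file's
#' 0-based half-open convention, which is also the package-internal one.
#' A missing or empty name column is replaced by a synthesized identifier
#' `"chrom:start-end"`. Malformed input is rejected, never repaired.
#'
#' @param path Path to a tab-separated BED3/BED6/narrowPeak file.
#' @param format One of `"bed"` or `"narrowPeak"` (both read the same leading
#'   columns; the argument documents intent and reserves stricter validation).
#' @return A `data.frame` with columns `peak_id`, `chrom`, `start`, `end`,
#'   `source_line` (1-based line number in the input file).
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("peak file does not exist: ", path)
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      source_line = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3L)) {
    bad <- line_no[which(n_col < 3L)[1L]]
    stop("malformed peak line ", bad, ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start_chr <- vapply(fields, `[[`, character(1), 2L)
  end_chr <- vapply(fields, `[[`, character(1), 3L)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad_coord <- is.na(start) | is.na(end) |
    start_chr != as.character(start) | end_chr != as.character(end)
  if (any(bad_coord)) {
    bad <- line_no[which(bad_coord)[1L]]
    stop("malformed peak line ", bad, ": coordinates do not parse as integers")
  }
  if (any(end <= start)) {
    bad <- line_no[which(end <= start)[1L]]
    stop("empty or inverted interval at line ", bad,
         ": end must be greater than start")
  }
  name <- ifelse(n_col >= 4L,
                 vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "",
                        character(1)),
                 "")
  explicit <- nzchar(name) & name != "."
  peak_id <- ifelse(explicit, name, paste0(chrom, ":", start, "-", end))
  if (anyDuplicated(peak_id[explicit])) {
    dup <- unique(peak_id[explicit][duplicated(peak_id[explicit])])
    stop("duplicate peak_id in ", path, ": ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(peak_id)) {
    dup <- unique(peak_id[duplicated(peak_id)])
    stop("duplicate (synthesized) peak_id in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  data.frame(peak_id = peak_id, chrom = chrom, start = start, end = end,
             source_line = line_no, stringsAsFactors = FALSE)
}

#' Write peaks to a BED file
#'
#' Inverse of [read_peaks()]: writes `chrom`, `start`, `end`, `peak_id` as
#' BED4, preserving the internal 0-based half-open coordinates, so that
#' read-write-read is the identity on records.
#'
#' @param peaks Peak `data.frame` as returned by [read_peaks()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(all(c("peak_id", "chrom", "start", "end") %in% names(peaks)))
  out <- sprintf("%s\t%d\t%d\t%s", peaks$chrom, peaks$start, peaks$end,
                 peaks$peak_id)
  writeLines(out, path)
  invisible(path)
}

#' Read a gene annotation with strand-aware TSS anchors
#'
#' Reads gene models from GTF or 6-column BED and derives, per gene, a
#' strand-aware transcription start site and a gene length for FPKM.
#' GTF coordinates (1-based, inclusive) are converted to the internal
#' 0-based half-open convention; BED6 is taken as-is. The TSS of a
#' plus-strand gene is `start`; of a minus-strand gene, `end - 1` (the
#' 3'-most file coordinate, i.e. the biological 5' end).
#'
#' @param path Path to a GTF or BED6 file.
#' @param format `"gtf"` or `"bed6"`.
#' @param feature GTF feature type to keep (default `"gene"`); ignored for
#'   BED6.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `gene_length` (all coordinates internal).
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed6"),
                                 feature = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("gene annotation file does not exist: ", path)
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf", feature.type = feature)
    if (length(gr) == 0L) {
      stop("no '", feature, "' records found in ", path)
    }
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(!strand %in% c("+", "-"))) {
      stop("unknown strand symbol in ", path,
           " (only '+' and '-' are accepted for genes)")
    }
    gene_id <- as.character(S4Vectors::mcols(gr)$gene_id)
    if (is.null(gene_id) || any(is.na(gene_id))) {
      stop("GTF records lack a gene_id attribute: ", path)
    }
    # GTF 1-based inclusive [s, e] -> internal 0-based half-open [s-1, e)
    start <- BiocGenerics::start(gr) - 1L
    end <- BiocGenerics::end(gr)
    chrom <- as.character(GenomeInfoDb::seqnames(gr))
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character",
                             comment.char = "#", quote = "")
    if (ncol(tab) < 6L) stop("BED6 annotation requires 6 columns: ", path)
    chrom <- tab[[1L]]
    start <- suppressWarnings(as.integer(tab[[2L]]))
    end <- suppressWarnings(as.integer(tab[[3L]]))
    if (any(is.na(start)) || any(is.na(end))) {
      stop("non-integer coordinates in ", path)
    }
    gene_id <- tab[[4L]]
    strand <- tab[[6L]]
    if (any(!strand %in% c("+", "-"))) {
      stop("unknown strand symbol in ", path,
           " (only '+' and '-' are accepted for genes)")
    }
  }
  if (any(end <= start)) {
    stop("gene with non-positive length in ", path, ": ",
         paste(utils::head(gene_id[end <= start], 3L), collapse = ", "))
  }
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("duplicate gene_id in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  tss <- ifelse(strand == "+", start, end - 1L)
  data.frame(gene_id = gene_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, tss = as.integer(tss),
             gene_length = as.integer(end - start),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation as GTF
#'
#' Serializes the internal gene table back to GTF `gene` records, converting
#' 0-based half-open coordinates to GTF's 1-based inclusive ones, so that the
#' GTF -> internal -> GTF round trip preserves file coordinates exactly.
#'
#' @param genes Gene `data.frame` as returned by [read_gene_annotation()].
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path, source = "acetylink") {
  out <- sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                 genes$chrom, source, genes$start + 1L, genes$end,
                 genes$strand, genes$gene_id)
  writeLines(out, path)
  invisible(path)
}

#' Read a TSV count matrix
#'
#' Reads a tab-separated matrix with a header row of sample identifiers and a
#' first column of feature identifiers. Cells must be non-negative integers;
#' anything else (negative, fractional, non-numeric, ragged rows) is an error.
#'
#' @param path Path to the TSV file.
#' @param feature_kind One of `"peak"`, `"gene"`, `"bin"`; stored as the
#'   `feature_kind` attribute of the result.
#' @return An integer matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path, feature_kind = c("peak", "gene", "bin")) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("count matrix file does not exist: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty count matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  # header may or may not carry a leading feature-column label
  n_body_col <- if (length(body)) lengths(body)[1L] else length(header)
  sample_ids <- if (length(header) == n_body_col) header[-1L] else header
  n_samples <- length(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample_id in header of ", path)
  if (length(body) && any(lengths(body) != n_samples + 1L)) {
    bad <- which(lengths(body) != n_samples + 1L)[1L] + 1L
    stop("ragged row at line ", bad, " of ", path)
  }
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(feature_ids)) stop("duplicate feature_id in ", path)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  num <- suppressWarnings(as.numeric(cells))
  if (any(is.na(num))) {
    stop("non-numeric count cell in ", path, ": '",
         cells[which(is.na(num))[1L]], "'")
  }
  if (any(num < 0)) {
    stop("negative count cell in ", path, ": ", num[which(num < 0)[1L]])
  }
  if (any(num != floor(num))) {
    stop("non-integer count cell in ", path, ": ",
         cells[which(num != floor(num))[1L]])
  }
  mat <- matrix(as.integer(num), nrow = length(body), ncol = n_samples,
                byrow = TRUE, dimnames = list(feature_ids, sample_ids))
  attr(mat, "feature_kind") <- feature_kind
  mat
}

#' Write a count matrix as TSV
#'
#' @param counts Integer matrix with feature rownames and sample colnames.
#' @param path Output file path.
#' @param feature_col Label for the leading feature-identifier column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, feature_col = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet maps each sequencing library to its biological condition
#' and assay and records its total mapped read count, which downstream
#' normalization uses as the library size (it is never recomputed from count
#' matrices, which cover only peaks or bins).
#'
#' @param path TSV with columns `sample_id`, `condition`, `assay`,
#'   `library_size`. `condition` must be one of `control`/`case` (aliases
#'   `ND` -> control, `MASLD`/`HFD` -> case are accepted); `assay` one of
#'   `chip`, `input`, `rna`.
#' @return A validated `data.frame` with those four columns.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  validate_sample_sheet(tab)
}

#' Validate a sample sheet data frame
#'
#' @param tab A `data.frame` with columns `sample_id`, `condition`, `assay`,
#'   `library_size`.
#' @return The validated (and condition-normalized) `data.frame`.
#' @export
validate_sample_sheet <- function(tab) {
  req <- c("sample_id", "condition", "assay", "library_size")
  missing_col <- setdiff(req, names(tab))
  if (length(missing_col)) {
    stop("sample sheet lacks column(s): ", paste(missing_col, collapse = ", "))
  }
  alias <- c(ND = "control", nd = "control", control = "control",
             MASLD = "case", masld = "case", HFD = "case", hfd = "case",
             case = "case")
  cond <- unname(alias[tab$condition])
  if (any(is.na(cond))) {
    stop("unknown condition label(s): ",
         paste(unique(tab$condition[is.na(cond)]), collapse = ", "))
  }
  tab$condition <- cond
  if (any(!tab$assay %in% c("chip", "input", "rna"))) {
    stop("unknown assay label(s): ",
         paste(unique(setdiff(tab$assay, c("chip", "input", "rna"))),
               collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in sample sheet")
  if (any(!is.finite(tab$library_size)) || any(tab$library_size <= 0) ||
      any(tab$library_size != floor(tab$library_size))) {
    stop("library_size must be a positive integer for every sample")
  }
  tab
}

.integration_cols <- c("peak_id", "gene_id", "distance_bp", "chip_log2fc",
                       "rna_log2fc", "pearson_r", "pearson_p", "correlated",
                       "quadrant")

#' Write the peak-gene integration table
#'
#' Serializes classified peak-gene links as TSV with columns `peak_id`,
#' `gene_id`, `distance_bp`, `chip_log2fc`, `rna_log2fc`, `pearson_r`,
#' `pearson_p`, `correlated`, `quadrant`. Numeric columns are written with
#' full precision (`format(..., digits = 17)`) so the file round-trips
#' losslessly through [read_integration_table()].
#'
#' @param links Link `data.frame` from the integration stage.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_integration_table <- function(links, path) {
  missing_col <- setdiff(.integration_cols, names(links))
  if (length(missing_col)) {
    stop("integration table lacks column(s): ",
         paste(missing_col, collapse = ", "))
  }
  out <- links[, .integration_cols, drop = FALSE]
  for (col in c("chip_log2fc", "rna_log2fc", "pearson_r", "pearson_p")) {
    out[[col]] <- vapply(out[[col]], function(x) {
      if (is.na(x)) "NA" else format(x, digits = 17, scientific = TRUE)
    }, character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak-gene integration table written by [write_integration_table()]
#'
#' @param path Path to the TSV file.
#' @return The link `data.frame`.
#' @export
read_integration_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(peak_id = "character",
                                          gene_id = "character",
                                          distance_bp = "integer",
                                          chip_log2fc = "numeric",
                                          rna_log2fc = "numeric",
                                          pearson_r = "numeric",
                                          pearson_p = "numeric",
                                          correlated = "logical",
                                          quadrant = "character"))
  missing_col <- setdiff(.integration_cols, names(tab))
  if (length(missing_col)) {
    stop("not an integration table (missing ",
         paste(missing_col, collapse = ", "), "): ", path)
  }
  tab
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated: set name, description, member ids.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("malformed GMT line (need name, description, >= 1 member): ", path)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set name in ", path)
  sets
}
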
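# Peak sets and gene models.
#
# Coordinate conventions, enforced at the readers:
#   * peaks (BED) are 0-based half-open [start, end)
#   * gene tables are 1-based inclusive on disk and converted to 0-based
#     half-open on read; the stored `tss` is the 0-based coordinate of the
#     first transcribed base (start on '+', end - 1 on '-').

#' Construct a peak set
#'
#' A peak set is a data frame of genomic intervals from one ChIP-seq
#' condition, with class `peak_set` and a `condition` attribute. Coordinates
#' are 0-based half-open. An optional per-peak `summit` (a single 0-based
#' position inside the peak) and `score` are carried when available.
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end` and
#'   optionally `peak_id`, `score`, `summit`.
#' @param condition Condition label (e.g. `"basal"`, `"induced"`).
#' @return A `peak_set` data frame.
#' @export
peak_set <- function(peaks, condition = "peaks") {
  if (!is.data.frame(peaks)) stopf("'peaks' must be a data frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stopf("peak set is missing column(s): %s",
                          paste(miss, collapse = ", "))
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  peaks$chrom <- as.character(peaks$chrom)
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  if (anyNA(peaks$start) || anyNA(peaks$end))
    stopf("peak coordinates must be integers")
  if (any(peaks$start >= peaks$end))
    stopf("all peaks must satisfy start < end (0-based half-open)")
  if (is.null(peaks$peak_id))
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  peaks$peak_id <- as.character(peaks$peak_id)
  if (anyDuplicated(peaks$peak_id))
    stopf("peak_ids must be unique within a peak set")
  if (is.null(peaks$score)) peaks$score <- rep(NA_real_, nrow(peaks))
  if (is.null(peaks$summit)) peaks$summit <- rep(NA_integer_, nrow(peaks))
  bad <- !is.na(peaks$summit) &
    (peaks$summit < peaks$start | peaks$summit >= peaks$end)
  if (any(bad))
    stopf("summit outside [start, end) for peak(s): %s",
          paste(utils::head(peaks$peak_id[bad], 3), collapse = ", "))
  peaks <- peaks[c("chrom", "start", "end", "peak_id", "score", "summit")]
  rownames(peaks) <- NULL
  structure(peaks, condition = condition,
            class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d peaks on %d chromosome(s)\n",
              attr(x, "condition"), nrow(x), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read / write BED peak files
#'
#' Reads a 3-6 column BED file (tab-separated, 0-based half-open) into a
#' [peak_set()]. Column 4 becomes `peak_id`, column 5 `score`; further
#' columns are ignored. Lines starting with `#`, `track` or `browser` are
#' skipped. `write_bed` emits chrom/start/end/peak_id/score (score written
#' as 0 when missing).
#'
#' @param path File path.
#' @param condition Condition label attached to the returned set.
#' @return `read_bed`: a `peak_set`. `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path, condition = sub("\\.bed$", "", basename(path))) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(peak_set(data.frame(chrom = character(0), start = integer(0),
                               end = integer(0)), condition))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stopf("BED line %d has fewer than 3 tab-separated fields", lineno[which(nf < 3)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stopf("BED line %d: malformed coordinates (non-integer or start >= end)",
          lineno[bad[1]])
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (any(nf >= 4)) df$peak_id <- vapply(fields, function(f)
    if (length(f) >= 4) f[[4]] else NA_character_, "")
  if (any(nf >= 5)) {
    sc <- vapply(fields, function(f)
      if (length(f) >= 5) f[[5]] else NA_character_, "")
    df$score <- suppressWarnings(as.numeric(sc))
  }
  peak_set(df, condition)
}

#' @rdname read_bed
#' @param x A `peak_set`.
#' @export
write_bed <- function(x, path) {
  x <- peak_set(x, attr(x, "condition") %||% "peaks")
  score <- ifelse(is.na(x$score), 0, x$score)
  out <- paste(x$chrom, x$start, x$end, x$peak_id,
               format(score, trim = TRUE, scientific = FALSE), sep = "\t")
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a gene-model table
#'
#' Validates a gene annotation and computes each gene's transcription start
#' site. Input coordinates are 1-based inclusive (the convention of gene
#' tables) by default and converted to 0-based half-open internally; the
#' TSS is the first transcribed base: `start` for `+` genes, `end` for `-`
#' genes.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end`.
#' @param coords `"1-based"` (inclusive, default for files on disk) or
#'   `"0-based"` (half-open, already internal).
#' @return Data frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open) and `tss` (0-based position), classed
#'   `gene_table`.
#' @export
gene_table <- function(genes, coords = c("1-based", "0-based")) {
  coords <- match.arg(coords)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stopf("gene table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (!all(genes$strand %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id))
    stopf("gene_ids must be unique within an annotation")
  if (coords == "1-based") {
    genes$start <- genes$start - 1L   # -> 0-based half-open
  }
  if (any(genes$start >= genes$end))
    stopf("all genes must satisfy start < end")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes <- genes[c("gene_id", "chrom", "strand", "start", "end", "tss")]
  rownames(genes) <- NULL
  structure(genes, class = c("gene_table", "data.frame"))
}

#' Read gene models
#'
#' `read_gene_table` reads a tab-separated file with header columns
#' `gene_id`, `chrom`, `strand`, `start`, `end` (1-based inclusive).
#' `read_gtf_genes` reads the `gene` features of a GTF file, taking
#' `gene_id` from the attribute string (GTF is 1-based inclusive).
#'
#' @param path File path.
#' @return A [gene_table()].
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stopf("gene table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_table(df, coords = "1-based")
}

#' @rdname read_gene_table
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[[3]] == "gene", TRUE)
  fields <- fields[keep]
  if (!length(fields)) stopf("no 'gene' features in GTF: %s", path)
  attr_id <- vapply(fields, function(f) {
    m <- regmatches(f[[9]], regexec('gene_id[ ]+"?([^";]+)"?', f[[9]]))[[1]]
    if (length(m) < 2) NA_character_ else m[[2]]
  }, "")
  if (anyNA(attr_id)) stopf("GTF gene feature without gene_id attribute")
  gene_table(data.frame(
    gene_id = attr_id,
    chrom = vapply(fields, `[[`, "", 1L),
    strand = vapply(fields, `[[`, "", 7L),
    start = as.integer(vapply(fields, `[[`, "", 4L)),
    end = as.integer(vapply(fields, `[[`, "", 5L)),
    stringsAsFactors = FALSE), coords = "1-based")
}

#' Write a gene table (1-based inclusive on disk)
#'
#' @param genes A [gene_table()].
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand,
                    start = genes$start + 1L,  # back to 1-based inclusive
                    end = genes$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Strand-oriented promoter window
#'
#' The promoter is the closed interval `[-upstream, +downstream]` of
#' oriented distances from the TSS, in the gene's transcriptional
#' direction; the default `(1000, 0)` is the window `-1000..0` bp.
#'
#' @param upstream,downstream Non-negative extents in bp; their sum must be
#'   positive.
#' @return List with class `promoter_window`.
#' @export
promoter_window <- function(upstream = 1000, downstream = 0) {
  assert_scalar_number(upstream, "upstream")
  assert_scalar_number(downstream, "downstream")
  if (upstream < 0 || downstream < 0)
    stopf("promoter window extents must be non-negative")
  if (upstream + downstream <= 0)
    stopf("promoter window must have positive total width")
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream)),
            class = "promoter_window")
}
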
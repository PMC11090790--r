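# Peak-to-gene assignment and peak-set comparison.

peak_anchor_positions <- function(peaks, anchor) {
  mid <- as.integer(floor((peaks$start + peaks$end) / 2))
  if (anchor == "summit") ifelse(is.na(peaks$summit), mid, peaks$summit)
  else mid
}

# Oriented distance from a gene's TSS to a genomic position: negative
# values are upstream of the TSS in the gene's transcriptional direction.
oriented_tss_distance <- function(pos, tss, strand) {
  ifelse(strand == "+", pos - tss, tss - pos)
}

#' Assign ChIP-seq peaks to genes
#'
#' Each peak is reduced to an anchor point (its summit when recorded, else
#' its midpoint) and assigned exactly one category:
#' \describe{
#'   \item{promoter}{the anchor lies within the strand-oriented promoter
#'     window of at least one gene, i.e. its oriented TSS distance `d`
#'     satisfies `-upstream <= d <= downstream`;}
#'   \item{gene_body}{otherwise, the anchor lies inside at least one gene
#'     body `[start, end)`;}
#'   \item{intergenic}{neither (including peaks on chromosomes absent from
#'     the annotation); `gene_id` and `tss_distance` are `NA`.}
#' }
#' Promoter beats gene body. When several genes are eligible in the winning
#' category, the gene with the smallest `|d|` is chosen, ties broken by
#' lexicographic `gene_id`, so the assignment is deterministic and
#' independent of input order.
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_table()].
#' @param window A [promoter_window()].
#' @param anchor `"summit"` (summit when present, midpoint fallback) or
#'   `"midpoint"`.
#' @return Data frame with one row per peak: `peak_id`, `gene_id`,
#'   `category`, `tss_distance` (oriented bp; negative = upstream).
#' @export
assign_peaks_to_genes <- function(peaks, genes,
                                  window = promoter_window(),
                                  anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  if (!inherits(window, "promoter_window"))
    window <- do.call(promoter_window, as.list(window))
  peaks <- peak_set(peaks, attr(peaks, "condition") %||% "peaks")
  if (!inherits(genes, "gene_table")) genes <- gene_table(genes, "0-based")
  n <- nrow(peaks)
  res <- data.frame(peak_id = peaks$peak_id,
                    gene_id = NA_character_,
                    category = "intergenic",
                    tss_distance = NA_integer_,
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(genes) == 0L) {
    res$category <- factor(res$category,
                           levels = c("promoter", "gene_body", "intergenic"))
    return(res)
  }
  pos <- peak_anchor_positions(peaks, anchor)
  anchor_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = pos + 1L, width = 1L))
  # closed promoter interval of 0-based positions, per gene
  prom_lo <- ifelse(genes$strand == "+",
                    genes$tss - window$upstream,
                    genes$tss - window$downstream)
  prom_hi <- ifelse(genes$strand == "+",
                    genes$tss + window$downstream,
                    genes$tss + window$upstream)
  prom_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = prom_lo + 1L, end = prom_hi + 1L))
  body_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end))

  pick_best <- function(hits, query_pos) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    if (!length(q)) return(NULL)
    d <- oriented_tss_distance(query_pos[q], genes$tss[s], genes$strand[s])
    ord <- order(q, abs(d), genes$gene_id[s], method = "radix")
    first <- !duplicated(q[ord])
    list(peak = q[ord][first], gene = s[ord][first], dist = d[ord][first])
  }

  prom <- pick_best(suppressWarnings(
    GenomicRanges::findOverlaps(anchor_gr, prom_gr)), pos)
  if (!is.null(prom)) {
    res$gene_id[prom$peak] <- genes$gene_id[prom$gene]
    res$category[prom$peak] <- "promoter"
    res$tss_distance[prom$peak] <- as.integer(prom$dist)
  }
  rest <- which(res$category == "intergenic")
  if (length(rest)) {
    body <- pick_best(suppressWarnings(
      GenomicRanges::findOverlaps(anchor_gr[rest], body_gr)), pos[rest])
    if (!is.null(body)) {
      idx <- rest[body$peak]
      res$gene_id[idx] <- genes$gene_id[body$gene]
      res$category[idx] <- "gene_body"
      res$tss_distance[idx] <- as.integer(body$dist)
    }
  }
  res$category <- factor(res$category,
                         levels = c("promoter", "gene_body", "intergenic"))
  res
}

#' Peak localization summary
#'
#' Counts and fractions of peak assignments per category (promoter,
#' gene body, intergenic).
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @return Data frame with `category`, `count`, `fraction`; fractions sum
#'   to 1.
#' @export
localization_summary <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0L)
    stopf("localization_summary: empty assignment table")
  tab <- table(assignments$category)
  data.frame(category = names(tab),
             count = as.integer(tab),
             fraction = as.numeric(tab) / nrow(assignments),
             stringsAsFactors = FALSE)
}

#' TSS-distance histogram
#'
#' Histogram of oriented TSS distances over all peak assignments that have
#' a gene, in bins `[i * bin_width, (i + 1) * bin_width)` anchored at 0.
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @param bin_width Positive bin width in bp.
#' @return Data frame with `bin_start`, `bin_end`, `count`; total count
#'   equals the number of gene-assigned peaks.
#' @export
tss_distance_profile <- function(assignments, bin_width = 500) {
  assert_scalar_number(bin_width, "bin_width")
  if (bin_width <= 0) stopf("bin_width must be positive")
  d <- assignments$tss_distance[!is.na(assignments$tss_distance)]
  if (!length(d))
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0)))
  idx <- floor(d / bin_width)
  tab <- table(idx)
  i <- as.integer(names(tab))
  data.frame(bin_start = i * as.integer(bin_width),
             bin_end = (i + 1L) * as.integer(bin_width),
             count = as.integer(tab))
}

#' Compare two peak sets
#'
#' Partitions each set into peaks shared with the other set (overlapping at
#' least one peak of the other set by `>= min_overlap_bp`) and unique
#' peaks, mirroring a two-set Venn analysis. The conserved fraction of `a`
#' is `|shared_a| / |a|`.
#'
#' @param a,b [peak_set()]s in the same coordinate convention.
#' @param min_overlap_bp Minimum overlap in bp (>= 1).
#' @return List with `peak_set`s `shared_a`, `unique_a`, `shared_b`,
#'   `unique_b`, and numbers `conserved_fraction_a`, `conserved_fraction_b`.
#' @export
peakset_overlap <- function(a, b, min_overlap_bp = 1) {
  assert_scalar_number(min_overlap_bp, "min_overlap_bp")
  if (min_overlap_bp < 1) stopf("min_overlap_bp must be >= 1")
  a <- peak_set(a, attr(a, "condition") %||% "a")
  b <- peak_set(b, attr(b, "condition") %||% "b")
  as_gr <- function(p) GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(start = p$start + 1L, end = p$end))
  shared_in <- function(x, y) {
    if (nrow(x) == 0L || nrow(y) == 0L) return(logical(nrow(x)))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      as_gr(x), as_gr(y), minoverlap = as.integer(min_overlap_bp)))
    seq_len(nrow(x)) %in% S4Vectors::queryHits(hits)
  }
  sa <- shared_in(a, b)
  sb <- shared_in(b, a)
  list(shared_a = a[sa, , drop = FALSE],
       unique_a = a[!sa, , drop = FALSE],
       shared_b = b[sb, , drop = FALSE],
       unique_b = b[!sb, , drop = FALSE],
       conserved_fraction_a = if (nrow(a)) mean(sa) else NA_real_,
       conserved_fraction_b = if (nrow(b)) mean(sb) else NA_real_)
}

#' Size of the merged-locus universe of several peak sets
#'
#' Default universe for the hypergeometric Venn test: all peaks of all sets
#' pooled and merged into maximal non-overlapping loci; the universe size
#' is the number of merged loci.
#'
#' @param ... [peak_set()]s.
#' @return Integer count of merged loci.
#' @export
peak_universe_size <- function(...) {
  sets <- list(...)
  if (!length(sets)) stopf("at least one peak set is required")
  grs <- lapply(sets, function(p) GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(start = p$start + 1L, end = p$end)))
  merged <- GenomicRanges::reduce(suppressWarnings(
    do.call(c, grs)))
  length(merged)
}
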
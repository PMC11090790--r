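# Signed, weighted transcription-factor regulons.

#' Construct a regulon
#'
#' A regulon is a transcription factor's target list. Each target has a
#' mode (+1 activated, -1 repressed, relative to TF activity) and a
#' confidence weight in `(0, 1]`.
#'
#' @param tf Transcription-factor name.
#' @param targets Data frame with columns `gene_id`, `mode`, `weight`.
#' @return List with class `regulon`.
#' @export
regulon <- function(tf, targets) {
  need <- c("gene_id", "mode", "weight")
  miss <- setdiff(need, names(targets))
  if (length(miss)) stopf("regulon targets missing column(s): %s",
                          paste(miss, collapse = ", "))
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  targets$gene_id <- as.character(targets$gene_id)
  targets$mode <- as.numeric(targets$mode)
  targets$weight <- as.numeric(targets$weight)
  if (anyDuplicated(targets$gene_id))
    stopf("regulon target gene_ids must be unique")
  if (!all(targets$mode %in% c(-1, 1)))
    stopf("regulon target mode must be -1 or +1")
  if (any(targets$weight <= 0 | targets$weight > 1))
    stopf("regulon target weights must be in (0, 1]")
  targets <- targets[order(targets$gene_id), c("gene_id", "mode", "weight")]
  rownames(targets) <- NULL
  structure(list(tf = as.character(tf), targets = targets),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("regulon '%s': %d targets (%d activated, %d repressed)\n",
              x$tf, nrow(x$targets), sum(x$targets$mode > 0),
              sum(x$targets$mode < 0)))
  invisible(x)
}

#' Build a lineage-specific regulon from binding and expression
#'
#' Implements an intersection-and-filter strategy: candidate targets are
#' the genes bound by the TF in every supplied cellular context; of those,
#' the targets are the genes passing the (strict) differential-expression
#' thresholds in a contrast that modulates TF activity. The regulation
#' mode is `sign(lfc) * tf_direction`, where `tf_direction = +1` means the
#' contrast raises TF activity (an induction experiment) and `-1` a
#' knock-down/knock-out contrast.
#'
#' @param bound_sets List of >= 2 character vectors of bound gene ids, one
#'   per cellular context.
#' @param de_table DE table for the TF-modulating contrast.
#' @param thresholds A [de_thresholds()]; defaults to the stringent filter
#'   `p < 0.001`, `|lfc| > 1`.
#' @param tf_direction `+1` or `-1` (see above).
#' @param tf_name Name recorded in the regulon.
#' @param weight_mode `"uniform"` (all weights 1) or `"pvalue"` (weight
#'   `1 - pvalue`, clamped into `(0, 1]`).
#' @param use_padj Filter on adjusted p-values instead of raw.
#' @return A [regulon()]. Errors (rather than returning silently) when the
#'   intersection-and-filter leaves no target.
#' @export
build_lineage_regulon <- function(bound_sets, de_table,
                                  thresholds = de_thresholds(),
                                  tf_direction = 1, tf_name = "TF",
                                  weight_mode = c("uniform", "pvalue"),
                                  use_padj = FALSE) {
  weight_mode <- match.arg(weight_mode)
  if (!is.list(bound_sets) || length(bound_sets) < 2)
    stopf("at least two bound-gene sets (cellular contexts) are required")
  if (!tf_direction %in% c(-1, 1)) stopf("tf_direction must be -1 or +1")
  de_table <- validate_de_table(de_table)
  candidates <- Reduce(intersect, lapply(bound_sets, assert_character_set,
                                         name = "bound_sets"))
  de <- select_de_genes(de_table, thresholds, use_padj = use_padj)
  keep <- intersect(candidates, c(de$up, de$down))
  if (!length(keep))
    stopf(paste0("empty regulon: no gene is bound in all %d contexts and ",
                 "differentially expressed at p < %g, |lfc| > %g"),
          length(bound_sets), thresholds$p_max, thresholds$lfc_min)
  rows <- de_table[match(keep, de_table$gene_id), ]
  weight <- switch(weight_mode,
                   uniform = rep(1, nrow(rows)),
                   pvalue = pmax(pmin(1 - rows$pvalue, 1), .Machine$double.eps))
  regulon(tf_name, data.frame(gene_id = rows$gene_id,
                              mode = sign(rows$lfc) * tf_direction,
                              weight = weight))
}

#' Overlap between two regulons
#'
#' @param a,b [regulon()]s.
#' @return List with `shared` (character vector of shared target genes) and
#'   `jaccard` (|intersection| / |union|, 0 when both are empty).
#' @export
regulon_overlap <- function(a, b) {
  ta <- a$targets$gene_id; tb <- b$targets$gene_id
  shared <- intersect(ta, tb)
  un <- union(ta, tb)
  list(shared = shared,
       jaccard = if (length(un)) length(shared) / length(un) else 0)
}

#' Read / write regulon TSV files
#'
#' The native format is tab-separated with header `tf`, `target`, `mode`,
#' `weight`; targets are written sorted by gene id. `read_regulon` can
#' also import other tabular regulon layouts (e.g. a DoRothEA-style table
#' with columns `tf`, `confidence`, `target`, `mor`) through `mapping`,
#' which names the columns holding each field; an unmapped `weight` gets
#' 1.
#'
#' @param path File path.
#' @param mapping Optional named list/vector with entries `tf`, `target`,
#'   `mode` and optionally `weight`, giving the column names in the file.
#' @return `read_regulon`: a [regulon()] (the file must contain a single
#'   TF).
#' @export
read_regulon <- function(path, mapping = NULL) {
  if (!file.exists(path)) stopf("regulon file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(mapping))
    mapping <- list(tf = "tf", target = "target", mode = "mode",
                    weight = "weight")
  for (f in c("tf", "target", "mode"))
    if (is.null(mapping[[f]]) || !mapping[[f]] %in% names(df))
      stopf("regulon file lacks a column for '%s'", f)
  tf <- unique(df[[mapping$tf]])
  if (length(tf) != 1)
    stopf("regulon file must contain exactly one TF (found %d)", length(tf))
  mode <- df[[mapping$mode]]
  mode <- sign(as.numeric(mode))  # DoRothEA 'mor' may carry magnitude
  if (any(mode == 0)) stopf("regulon mode must be non-zero (-1/+1)")
  weight <- if (!is.null(mapping$weight) && mapping$weight %in% names(df))
    as.numeric(df[[mapping$weight]]) else rep(1, nrow(df))
  regulon(tf, data.frame(gene_id = df[[mapping$target]], mode = mode,
                         weight = weight))
}

#' @rdname read_regulon
#' @param x A [regulon()].
#' @export
write_regulon <- function(x, path) {
  t <- x$targets[order(x$targets$gene_id), ]
  out <- data.frame(tf = x$tf, target = t$gene_id, mode = t$mode,
                    weight = t$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a regulon as a pair of gene signatures
#'
#' Two GMT-ready signatures: `<tf>_up` (activated targets) and
#' `<tf>_down` (repressed targets). Empty sides are omitted.
#'
#' @param x A [regulon()].
#' @return Named list of [gene_signature()]s.
#' @export
regulon_to_gmt <- function(x) {
  sigs <- list()
  up <- x$targets$gene_id[x$targets$mode > 0]
  dn <- x$targets$gene_id[x$targets$mode < 0]
  if (length(up))
    sigs[[paste0(x$tf, "_up")]] <-
      gene_signature(paste0(x$tf, "_up"), up, direction = "up")
  if (length(dn))
    sigs[[paste0(x$tf, "_down")]] <-
      gene_signature(paste0(x$tf, "_down"), dn, direction = "down")
  sigs
}
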
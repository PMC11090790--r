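# Integration of bound-gene sets with differential expression.

#' Differential-expression thresholds
#'
#' Strict thresholds for calling a gene differentially expressed:
#' `pvalue < p_max` and `|lfc| > lfc_min`. The defaults (0.001, 1) are the
#' conventional stringent filter for log2 fold-changes.
#'
#' @param p_max Maximum p-value, in `(0, 1)`.
#' @param lfc_min Minimum absolute log2 fold-change, `>= 0`.
#' @return List with class `de_thresholds`.
#' @export
de_thresholds <- function(p_max = 0.001, lfc_min = 1) {
  assert_scalar_number(p_max, "p_max")
  assert_scalar_number(lfc_min, "lfc_min")
  if (p_max <= 0 || p_max >= 1) stopf("p_max must be in (0, 1)")
  if (lfc_min < 0) stopf("lfc_min must be >= 0")
  structure(list(p_max = p_max, lfc_min = lfc_min), class = "de_thresholds")
}

validate_de_table <- function(de) {
  need <- c("gene_id", "lfc", "pvalue")
  miss <- setdiff(need, names(de))
  if (length(miss)) stopf("DE table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  de <- as.data.frame(de, stringsAsFactors = FALSE)
  de$gene_id <- as.character(de$gene_id)
  if (anyDuplicated(de$gene_id)) stopf("DE table gene_ids must be unique")
  if (any(!is.finite(de$lfc))) stopf("DE table lfc must be finite")
  if (any(de$pvalue <= 0 | de$pvalue > 1))
    stopf("DE table pvalues must be in (0, 1]")
  de
}

#' Read a differential-expression table
#'
#' Tab-separated file with header columns `gene_id`, `lfc` (signed log2
#' fold-change) and `pvalue`, optionally `padj`.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stopf("DE table not found: %s", path)
  validate_de_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Select differentially expressed genes
#'
#' Applies strict thresholds: up-regulated genes have `p < p_max` and
#' `lfc > +lfc_min`; down-regulated genes `p < p_max` and
#' `lfc < -lfc_min`. Boundary values (`p == p_max`, `|lfc| == lfc_min`)
#' are excluded.
#'
#' @param de DE table (see [read_de_table()]).
#' @param thresholds A [de_thresholds()].
#' @param use_padj Filter on the `padj` column instead of raw `pvalue`.
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
select_de_genes <- function(de, thresholds = de_thresholds(),
                            use_padj = FALSE) {
  de <- validate_de_table(de)
  if (!inherits(thresholds, "de_thresholds"))
    thresholds <- do.call(de_thresholds, as.list(thresholds))
  if (nrow(de) == 0L) stopf("DE table is empty")
  p <- if (use_padj) {
    if (is.null(de$padj)) stopf("use_padj = TRUE but no 'padj' column")
    de$padj
  } else de$pvalue
  sig <- p < thresholds$p_max
  list(up = de$gene_id[sig & de$lfc > thresholds$lfc_min],
       down = de$gene_id[sig & de$lfc < -thresholds$lfc_min])
}

#' Bound fraction among DE genes, with enrichment tests
#'
#' For each class of genes (all DE, up, down, and the non-DE background)
#' reports the fraction carrying a binding peak and an upper-tail
#' hypergeometric enrichment p-value against the given universe.
#'
#' @param up,down Character vectors of up-/down-regulated gene ids.
#' @param bound Character vector of bound gene ids.
#' @param universe Character vector of all genes considered.
#' @return Data frame with `class`, `n`, `n_bound`, `fraction`, `p_enrich`.
#' @export
bound_fraction_report <- function(up, down, bound, universe) {
  universe <- assert_character_set(universe, "universe")
  if (!length(universe)) stopf("gene universe must be non-empty")
  up <- intersect(assert_character_set(up, "up"), universe)
  down <- intersect(assert_character_set(down, "down"), universe)
  bound <- intersect(assert_character_set(bound, "bound"), universe)
  classes <- list(all_de = union(up, down), up = up, down = down,
                  background = setdiff(universe, union(up, down)))
  rows <- lapply(names(classes), function(nm) {
    g <- classes[[nm]]
    nb <- length(intersect(g, bound))
    data.frame(class = nm, n = length(g), n_bound = nb,
               fraction = if (length(g)) nb / length(g) else NA_real_,
               p_enrich = if (length(g))
                 hypergeometric_overlap_test(nb, length(bound), length(g),
                                             length(universe))
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify per-gene binding dynamics across two conditions
#'
#' Genes are `conserved` when bound in both conditions, `de_novo` when
#' bound only after induction, `lost` when bound only at baseline, and
#' `unbound` otherwise; the statuses partition the universe. Fractions of
#' the induced-bound set (conserved + de novo) are also reported.
#'
#' @param bound_basal,bound_induced Character vectors of bound gene ids.
#' @param universe Character vector of all genes considered.
#' @return List with `status` (data frame `gene_id`, `status`) and
#'   `induced_fractions` (named vector over conserved/de_novo).
#' @export
classify_binding_dynamics <- function(bound_basal, bound_induced, universe) {
  universe <- assert_character_set(universe, "universe")
  bound_basal <- intersect(assert_character_set(bound_basal, "bound_basal"),
                           universe)
  bound_induced <- intersect(
    assert_character_set(bound_induced, "bound_induced"), universe)
  in_b <- universe %in% bound_basal
  in_i <- universe %in% bound_induced
  status <- ifelse(in_b & in_i, "conserved",
            ifelse(in_i, "de_novo",
            ifelse(in_b, "lost", "unbound")))
  n_ind <- sum(in_i)
  fr <- c(conserved = if (n_ind) sum(in_b & in_i) / n_ind else NA_real_,
          de_novo = if (n_ind) sum(!in_b & in_i) / n_ind else NA_real_)
  list(status = data.frame(gene_id = universe, status = status,
                           stringsAsFactors = FALSE),
       induced_fractions = fr)
}

#' Bound genes of a peak assignment
#'
#' Convenience accessor: unique genes carrying at least one assigned peak
#' (promoter and/or gene body).
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @param categories Categories that count as binding.
#' @return Character vector of gene ids.
#' @export
bound_genes <- function(assignments,
                        categories = c("promoter", "gene_body")) {
  keep <- assignments$category %in% categories & !is.na(assignments$gene_id)
  sort(unique(assignments$gene_id[keep]))
}
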
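# Gene signatures: GMT I/O, binding coverage, ssGSEA.

#' Construct a gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of gene ids (deduplicated, order kept).
#' @param direction `"up"`, `"down"` or `"unsigned"`.
#' @param description Free-text description (second GMT column).
#' @return List with class `gene_signature`.
#' @export
gene_signature <- function(name, genes,
                           direction = c("unsigned", "up", "down"),
                           description = "") {
  direction <- match.arg(direction)
  genes <- unique(as.character(genes))
  if (!length(genes)) stopf("signature '%s' has no genes", name)
  structure(list(name = as.character(name), genes = genes,
                 direction = direction, description = description),
            class = "gene_signature")
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: name, description, then one gene per field.
#' Duplicate genes within a line are collapsed.
#'
#' @param path File path.
#' @return `read_gmt`: named list of [gene_signature()]s.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stopf("GMT line %d has fewer than 3 tab-separated fields", i)
    gene_signature(f[[1]], f[-(1:2)], description = f[[2]])
  })
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  sigs
}

#' @rdname read_gmt
#' @param signatures List of [gene_signature()]s.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  out <- vapply(signatures, function(s)
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$genes), collapse = "\t"), "")
  writeLines(out, path)
  invisible(path)
}

#' Binding coverage of a signature
#'
#' Percentage of signature genes carrying a binding peak, per condition.
#'
#' @param signature A [gene_signature()] or character vector of genes.
#' @param bound Named list of bound-gene character vectors, one per
#'   condition (a single character vector is treated as one condition).
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
signature_peak_coverage <- function(signature, bound) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else unique(as.character(signature))
  if (!length(genes)) stopf("signature must be non-empty")
  if (!is.list(bound)) bound <- list(bound = bound)
  vapply(bound, function(b)
    100 * length(intersect(genes, b)) / length(genes), numeric(1))
}

#' ssGSEA parameters
#'
#' @param weight_exponent Exponent applied to the absolute rank statistic
#'   of in-set genes (0 gives unweighted Kolmogorov-Smirnov-style sums).
#' @param normalization `"none"` or `"global_range"` (matrix entries
#'   divided by the global max - min after scoring).
#' @return List with class `ssgsea_params`.
#' @export
ssgsea_params <- function(weight_exponent = 0.25,
                          normalization = c("none", "global_range")) {
  assert_scalar_number(weight_exponent, "weight_exponent")
  if (weight_exponent < 0) stopf("weight_exponent must be >= 0")
  structure(list(weight_exponent = weight_exponent,
                 normalization = match.arg(normalization)),
            class = "ssgsea_params")
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum score of one gene set in one expression profile.
#' Genes are ordered by decreasing expression (midranks for ties, ties in
#' order broken by gene id for determinism). Walking down the list, the
#' score is the sum over all positions of the difference between the
#' weighted empirical distribution of in-set genes (weights
#' `|rank|^weight_exponent`) and the unweighted distribution of out-of-set
#' genes. The score depends on the profile only through ranks, so any
#' strictly increasing transform of the expression values leaves it
#' unchanged.
#'
#' @param profile Named numeric vector of expression values (>= 2 genes).
#' @param signature A [gene_signature()] or character vector. Signature
#'   genes absent from the profile are dropped (with a message when
#'   `verbose`).
#' @param params An [ssgsea_params()].
#' @param verbose Report the number of dropped signature genes.
#' @return A single numeric score.
#' @export
ssgsea_score <- function(profile, signature, params = ssgsea_params(),
                         verbose = FALSE) {
  if (!inherits(params, "ssgsea_params"))
    params <- do.call(ssgsea_params, as.list(params))
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else unique(as.character(signature))
  if (is.null(names(profile)) || length(profile) < 2)
    stopf("profile must be a named numeric vector over >= 2 genes")
  n <- length(profile)
  in_sig <- names(profile) %in% genes
  dropped <- length(setdiff(genes, names(profile)))
  if (verbose && dropped)
    message(sprintf("ssgsea_score: %d signature gene(s) not in profile",
                    dropped))
  k <- sum(in_sig)
  if (k == 0L) stopf("signature has no overlap with the profile")
  if (k == n) stopf("signature covers the whole profile (degenerate)")
  r <- rank(profile, ties.method = "average")
  ord <- order(-r, names(profile), method = "radix")
  in_set <- in_sig[ord]
  w <- abs(r[ord])^params$weight_exponent
  p_in <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
  p_out <- cumsum(!in_set) / (n - k)
  sum(p_in - p_out)
}

#' Score several signatures across all columns of an expression matrix
#'
#' @param expr Numeric matrix, genes in rows (rownames required), samples
#'   or cells in columns.
#' @param signatures List of [gene_signature()]s (or character vectors).
#' @param params An [ssgsea_params()]; with `normalization =
#'   "global_range"` the full matrix is divided by its max - min.
#' @param on_error `"fail"` stops on a signature/column error;
#'   `"warn"` records `NA` and carries on.
#' @return Numeric matrix, signatures x columns.
#' @export
ssgsea_matrix <- function(expr, signatures, params = ssgsea_params(),
                          on_error = c("fail", "warn")) {
  on_error <- match.arg(on_error)
  if (!inherits(params, "ssgsea_params"))
    params <- do.call(ssgsea_params, as.list(params))
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stopf("expression matrix needs rownames")
  if (anyNA(expr)) stopf("expression matrix must be complete (no NA)")
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  sig_names <- vapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    if (inherits(s, "gene_signature")) s$name
    else names(signatures)[i] %||% sprintf("set%d", i)
  }, "")
  out <- matrix(NA_real_, nrow = length(signatures), ncol = ncol(expr),
                dimnames = list(sig_names, colnames(expr)))
  for (i in seq_along(signatures)) {
    for (j in seq_len(ncol(expr))) {
      val <- tryCatch(
        ssgsea_score(stats::setNames(expr[, j], rownames(expr)),
                     signatures[[i]], params),
        error = function(e) {
          if (on_error == "fail") stop(e)
          warnf("ssgsea_matrix: %s (signature '%s', column %d)",
                conditionMessage(e), sig_names[i], j)
          NA_real_
        })
      out[i, j] <- val
    }
  }
  if (params$normalization == "global_range") {
    rng <- range(out, na.rm = TRUE)
    if (diff(rng) > 0) out <- out / diff(rng)
  }
  out
}

#' Read an expression matrix from TSV
#'
#' Tab-separated, first column = gene ids, remaining columns = samples or
#' cells.
#'
#' @param path File path.
#' @return Numeric matrix with rownames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param expr Numeric matrix with rownames.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
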
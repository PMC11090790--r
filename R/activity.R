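# Regulon activity scoring: rank signatures, enrichment scores, NES.

#' Build a rank signature from a contrast or an expression profile
#'
#' A rank signature maps every gene to a real statistic against which
#' regulon enrichment is scored.
#' \describe{
#'   \item{signed_stat}{for a DE contrast: `sign(lfc) * (-log10 p)`,
#'     capped at `+/- cap` so `p = 0` cannot produce infinities.}
#'   \item{percell_rank}{for one expression column: the within-profile
#'     midrank quantile, mapped through the standard-normal quantile
#'     function (`qnorm((r - 0.5) / n)`). The median gene of an odd-sized
#'     profile scores exactly 0.}
#' }
#'
#' @param source A DE table (for `signed_stat`) or a named numeric
#'   expression vector (for `percell_rank`).
#' @param method Signature construction method.
#' @param cap Cap on `|score|` for `signed_stat`.
#' @return Named numeric vector (the signature), one value per gene.
#' @export
make_rank_signature <- function(source,
                                method = c("signed_stat", "percell_rank"),
                                cap = 10) {
  method <- match.arg(method)
  if (method == "signed_stat") {
    de <- validate_de_table(source)
    if (nrow(de) < 3) stopf("signature needs >= 3 genes")
    score <- sign(de$lfc) * pmin(-log10(de$pvalue), cap)
    return(stats::setNames(score, de$gene_id))
  }
  x <- source
  if (is.null(names(x)) || !is.numeric(x))
    stopf("percell_rank needs a named numeric expression vector")
  if (length(x) < 3) stopf("signature needs >= 3 genes")
  if (length(unique(x)) == 1L) {
    warnf("constant profile: degenerate signature, all scores 0")
    return(stats::setNames(rep(0, length(x)), names(x)))
  }
  r <- rank(x, ties.method = "average")
  stats::setNames(stats::qnorm((r - 0.5) / length(x)), names(x))
}

signature_zscores <- function(sig) {
  # midrank-based standard-normal quantiles of the signature values;
  # shared by enrichment_score and the permutation null
  n <- length(sig)
  r <- rank(sig, ties.method = "average")
  stats::setNames(stats::qnorm((r - 0.5) / n), names(sig))
}

#' Two-tailed weighted regulon enrichment score
#'
#' Every gene of the signature namespace receives a z-score, the
#' standard-normal quantile of its midrank within the signature. The
#' enrichment score of a regulon is the weighted mean of its targets'
#' z-scores, with repressed targets (mode -1) contributing with flipped
#' sign:
#' `es = sum(mode * weight * z) / sum(weight)`.
#' Negating every mode therefore negates the score exactly.
#'
#' @param sig Named numeric rank signature (see [make_rank_signature()]).
#' @param regulon A [regulon()]; targets absent from the signature
#'   namespace are dropped.
#' @return A single numeric enrichment score.
#' @export
enrichment_score <- function(sig, regulon) {
  z <- signature_zscores(sig)
  t <- regulon$targets[regulon$targets$gene_id %in% names(z), ]
  if (!nrow(t))
    stopf("regulon '%s' has no target in the signature namespace",
          regulon$tf)
  sum(t$mode * t$weight * z[t$gene_id]) / sum(t$weight)
}

#' Normalized enrichment score (NES) of a regulon in a signature
#'
#' Standardizes the enrichment score against a null in which the regulon's
#' targets are random genes of the signature namespace.
#' \describe{
#'   \item{analytic}{`nes = es * sum(w) / sqrt(sum(w^2))` - exact when the
#'     z-scores are standard-normal quantiles, since the weighted mean of
#'     independent standard normals has standard deviation
#'     `sqrt(sum(w^2)) / sum(w)`.}
#'   \item{permutation}{`nes = (es - mean) / sd` over `n_perm` gene-label
#'     permutations of the signature namespace, drawn from a generator
#'     seeded with `seed` (reproducible).}
#' }
#'
#' @param sig Named numeric rank signature.
#' @param regulon A [regulon()].
#' @param null `"analytic"` or `"permutation"`.
#' @param n_perm Number of permutations (>= 100) for the permutation null.
#' @param seed Integer seed for the permutation null.
#' @return List with class `activity_result`: `tf`, `es`, `nes`,
#'   `null_kind`, `n_perm`, `seed`.
#' @export
nes <- function(sig, regulon, null = c("analytic", "permutation"),
                n_perm = 1000, seed = 1) {
  null <- match.arg(null)
  z <- signature_zscores(sig)
  t <- regulon$targets[regulon$targets$gene_id %in% names(z), ]
  if (!nrow(t))
    stopf("regulon '%s' has no target in the signature namespace",
          regulon$tf)
  w <- t$weight
  es <- sum(t$mode * w * z[t$gene_id]) / sum(w)
  if (null == "analytic") {
    val <- es * sum(w) / sqrt(sum(w^2))
    return(structure(list(tf = regulon$tf, es = es, nes = val,
                          null_kind = "analytic", n_perm = 0L,
                          seed = NA_integer_),
                     class = "activity_result"))
  }
  if (n_perm < 100) stopf("permutation null needs n_perm >= 100")
  if (nrow(t) >= length(z))
    stopf("degenerate permutation null: regulon covers the whole namespace")
  k <- nrow(t)
  sw <- sum(w)
  mw <- t$mode * w
  perm_es <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      sum(mw * z[sample.int(length(z), k)]) / sw, numeric(1))
  })
  s <- stats::sd(perm_es)
  if (!is.finite(s) || s == 0)
    stopf("degenerate permutation null: zero variance")
  structure(list(tf = regulon$tf, es = es,
                 nes = (es - mean(perm_es)) / s,
                 null_kind = "permutation", n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "activity_result")
}

# evaluate `code` under a local, restored RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("activity of '%s': es = %.4f, nes = %.4f (%s null%s)\n",
              x$tf, x$es, x$nes, x$null_kind,
              if (x$null_kind == "permutation")
                sprintf(", %d perms, seed %d", x$n_perm, x$seed) else ""))
  invisible(x)
}

#' Regulon activity across all columns of an expression matrix
#'
#' Builds a per-cell rank signature (`percell_rank`) for every column and
#' scores every regulon against it, returning a regulon x column matrix of
#' NES values. Optional grouping labels are attached for downstream group
#' summaries.
#'
#' @param expr Numeric matrix, genes x samples/cells, with dimnames.
#' @param regulons A [regulon()] or list of regulons.
#' @param null,n_perm,seed Passed to [nes()] (analytic by default; the
#'   permutation null re-seeds per column with `seed + column index`).
#' @param groups Optional vector of per-column group labels, attached as
#'   attribute `"groups"`.
#' @param on_error `"fail"` or `"warn"` (score recorded as `NA`).
#' @return Numeric matrix of NES values with attribute `"groups"`.
#' @export
activity_matrix <- function(expr, regulons, null = "analytic",
                            n_perm = 1000, seed = 1, groups = NULL,
                            on_error = c("fail", "warn")) {
  on_error <- match.arg(on_error)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stopf("expression matrix needs rownames")
  if (inherits(regulons, "regulon")) regulons <- list(regulons)
  rn <- vapply(regulons, `[[`, "", "tf")
  if (!is.null(groups) && length(groups) != ncol(expr))
    stopf("'groups' must have one label per column")
  out <- matrix(NA_real_, nrow = length(regulons), ncol = ncol(expr),
                dimnames = list(rn, colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    sig <- make_rank_signature(stats::setNames(expr[, j], rownames(expr)),
                               method = "percell_rank")
    for (i in seq_along(regulons)) {
      val <- tryCatch(
        nes(sig, regulons[[i]], null = null, n_perm = n_perm,
            seed = seed + j)$nes,
        error = function(e) {
          if (on_error == "fail") stop(e)
          warnf("activity_matrix: %s (regulon '%s', column %d)",
                conditionMessage(e), rn[i], j)
          NA_real_
        })
      out[i, j] <- val
    }
  }
  attr(out, "groups") <- groups
  out
}
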
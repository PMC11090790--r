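# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}

assert_character_set <- function(x, name) {
  if (is.null(x)) return(character(0))
  if (!is.character(x)) stopf("'%s' must be a character vector of gene ids", name)
  unique(x)
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of observing `k` or more shared elements when two subsets of
#' sizes `n_a` and `n_b` are drawn without replacement from a universe of
#' `universe_n` elements. This is the significance test used for Venn-style
#' overlaps of peak sets or gene sets.
#'
#' @param k Observed overlap (non-negative integer).
#' @param n_a,n_b Sizes of the two sets.
#' @param universe_n Size of the universe both sets are drawn from.
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeometric_overlap_test(4, 4, 5, 10)
#' @export
hypergeometric_overlap_test <- function(k, n_a, n_b, universe_n) {
  for (nm in c("k", "n_a", "n_b", "universe_n"))
    assert_scalar_number(get(nm), nm)
  if (k < 0 || n_a < 0 || n_b < 0 || universe_n < 0)
    stopf("hypergeometric margins must be non-negative")
  if (n_a > universe_n || n_b > universe_n)
    stopf("set sizes (%d, %d) exceed the universe (%d)", n_a, n_b, universe_n)
  if (k > min(n_a, n_b))
    stopf("observed overlap k=%d exceeds min(n_a, n_b)=%d", k, min(n_a, n_b))
  if (k < max(0, n_a + n_b - universe_n))
    stopf("observed overlap k=%d is below the forced minimum %d",
          k, max(0, n_a + n_b - universe_n))
  # P(X >= k) with X ~ Hypergeometric(n_a successes, universe_n - n_a
  # failures, n_b draws)
  stats::phyper(k - 1, n_a, universe_n - n_a, n_b, lower.tail = FALSE)
}
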
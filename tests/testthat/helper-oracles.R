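# Independent oracles: brute-force / exhaustive re-implementations used to
# check the package's optimized code paths. They deliberately share no code
# with the package internals.

# Quadratic all-pairs peak-to-gene assignment.
oracle_assign <- function(peaks, genes, upstream = 1000, downstream = 0,
                          anchor = "summit") {
  mid <- floor((peaks$start + peaks$end) / 2)
  pos <- if (anchor == "summit") ifelse(is.na(peaks$summit), mid,
                                        peaks$summit) else mid
  res <- data.frame(peak_id = peaks$peak_id, gene_id = NA_character_,
                    category = "intergenic", tss_distance = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    same_chr <- genes$chrom == peaks$chrom[i]
    if (!any(same_chr)) next
    g <- genes[same_chr, ]
    d <- ifelse(g$strand == "+", pos[i] - g$tss, g$tss - pos[i])
    in_prom <- d >= -upstream & d <= downstream
    in_body <- pos[i] >= g$start & pos[i] < g$end
    pick <- function(mask) {
      cand <- which(mask)
      cand[order(abs(d[cand]), g$gene_id[cand])][1]
    }
    if (any(in_prom)) {
      j <- pick(in_prom)
      res$gene_id[i] <- g$gene_id[j]
      res$category[i] <- "promoter"
      res$tss_distance[i] <- d[j]
    } else if (any(in_body)) {
      j <- pick(in_body)
      res$gene_id[i] <- g$gene_id[j]
      res$category[i] <- "gene_body"
      res$tss_distance[i] <- d[j]
    }
  }
  res
}

# Quadratic peak-set overlap partition.
oracle_overlap <- function(a, b, min_bp = 1) {
  hit <- function(x, y) {
    vapply(seq_len(nrow(x)), function(i) {
      same <- y$chrom == x$chrom[i]
      any(pmin(y$end[same], x$end[i]) - pmax(y$start[same], x$start[i]) >=
            min_bp)
    }, logical(1))
  }
  list(shared_a = hit(a, b), shared_b = hit(b, a))
}

# Exhaustive hypergeometric upper tail: fix set A = first n_a elements,
# enumerate every draw of n_b elements from the universe.
oracle_hyper <- function(k, n_a, n_b, universe_n) {
  draws <- combn(universe_n, n_b)
  overlaps <- colSums(draws <= n_a)
  mean(overlaps >= k)
}

# Independent running-sum re-implementation of the single-sample
# enrichment score (explicit walk down the ranked list).
oracle_ssgsea <- function(profile, set_genes, alpha = 0.25) {
  r <- rank(profile, ties.method = "average")
  ord <- order(-r, names(profile))
  nm <- names(profile)[ord]
  hits <- nm %in% set_genes
  n <- length(nm); k <- sum(hits)
  denom <- sum(abs(r[ord][hits])^alpha)
  p_in <- 0; p_out <- 0; es <- 0
  for (i in seq_len(n)) {
    if (hits[i]) p_in <- p_in + abs(r[ord][i])^alpha / denom
    else p_out <- p_out + 1 / (n - k)
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Direct evaluation of the two-tailed weighted enrichment score from its
# definition (no shared helper).
oracle_es <- function(sig, modes, weights, target_genes) {
  n <- length(sig)
  z <- qnorm((rank(sig, ties.method = "average") - 0.5) / n)
  names(z) <- names(sig)
  sum(modes * weights * z[target_genes]) / sum(weights)
}

# Exhaustive permutation null of the enrichment score: every assignment of
# k target slots to distinct namespace genes (ordered, since modes and
# weights differ per slot).
oracle_exhaustive_null <- function(sig, modes, weights, k) {
  n <- length(sig)
  z <- qnorm((rank(sig, ties.method = "average") - 0.5) / n)
  idx <- combn(n, k)
  perms_of <- function(v) {
    if (length(v) == 1) return(matrix(v))
    do.call(cbind, lapply(seq_along(v), function(i)
      rbind(v[i], perms_of(v[-i]))))
  }
  es <- c(apply(idx, 2, function(cols) {
    apply(perms_of(cols), 2, function(ord)
      sum(modes * weights * z[ord]) / sum(weights))
  }))
  c(mean = mean(es), sd = sd(es) * sqrt((length(es) - 1) / length(es)))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments,
# using the same two-sided rule as R's exact wilcox.test.
oracle_wilcox <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  w_obs <- sum(vapply(x, function(xi) sum(xi > y), 1.0))
  all_w <- apply(combn(length(pooled), n1), 2, function(ix) {
    a <- pooled[ix]; b <- pooled[-ix]
    sum(vapply(a, function(ai) sum(ai > b), 1.0))
  })
  p_le <- mean(all_w <= w_obs)
  p_ge <- mean(all_w >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact binomial 99% acceptance band for a count of successes.
binom_band99 <- function(n, p) qbinom(c(0.005, 0.995), n, p)

expect_in_binom_band <- function(k, n, p) {
  band <- binom_band99(n, p)
  expect_true(k >= band[1] && k <= band[2],
              label = sprintf("count %d within binomial 99%% band [%d, %d] (n=%d, p=%.3f)",
                              k, band[1], band[2], n, p))
}

# Random fixture builders -----------------------------------------------

random_genes <- function(n, chroms = c("chrA", "chrB"), len = 1e6) {
  start <- sample.int(len - 30000, n, replace = TRUE) + 10000
  gene_table(data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = start, end = start + sample(1000:20000, n, replace = TRUE),
    stringsAsFactors = FALSE), coords = "0-based")
}

random_peaks <- function(n, chroms = c("chrA", "chrB"), len = 1e6,
                         condition = "rand", with_summit = TRUE) {
  start <- sample.int(len - 2000, n, replace = TRUE)
  width <- sample(100:800, n, replace = TRUE)
  summit <- if (with_summit) start + sample.int(99, n, replace = TRUE)
            else NA_integer_
  peak_set(data.frame(chrom = sample(chroms, n, replace = TRUE),
                      start = start, end = start + width,
                      peak_id = sprintf("p%04d", seq_len(n)),
                      score = runif(n), summit = summit,
                      stringsAsFactors = FALSE), condition)
}
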
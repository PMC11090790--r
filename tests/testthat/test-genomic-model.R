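# Gene models, peak I/O, promoter assignment and peak-set comparison.

test_that("BED reader maps fields and rejects malformed coordinates", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment", "chr1\t100\t200",
               "chr2\t50\t80\tmypeak\t7.5"), tmp)
  ps <- read_bed(tmp)
  expect_equal(nrow(ps), 2L)
  expect_equal(ps$chrom, c("chr1", "chr2"))
  expect_equal(ps$start, c(100L, 50L))
  expect_equal(ps$end, c(200L, 80L))
  expect_equal(ps$peak_id[2], "mypeak")
  expect_equal(ps$score[2], 7.5)

  writeLines("chr1\t300\t200", tmp)
  expect_error(read_bed(tmp), "line 1")
  writeLines(c("chr1\t100\t200", "chr1\tx\t200"), tmp)
  expect_error(read_bed(tmp), "line 2")

  writeLines(character(0), tmp)
  expect_equal(nrow(read_bed(tmp)), 0L)
})

test_that("write_bed / read_bed round-trips a 50-peak synthetic file", {
  set.seed(71)
  ps <- random_peaks(50, with_summit = FALSE)
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, tmp)
  back <- read_bed(tmp)
  expect_equal(back$chrom, ps$chrom)
  expect_equal(back$start, ps$start)
  expect_equal(back$end, ps$end)
  expect_equal(back$peak_id, ps$peak_id)
  # a second write is byte-identical
  tmp2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("gene tables convert 1-based coordinates and locate the TSS", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\tstart\tend",
               "gA\tchr1\t+\t1001\t2000",
               "gB\tchr1\t-\t5001\t6000"), tmp)
  g <- read_gene_table(tmp)
  expect_equal(g$start, c(1000L, 5000L))  # 0-based half-open
  expect_equal(g$end, c(2000L, 6000L))
  expect_equal(g$tss, c(1000L, 5999L))    # first transcribed base
  expect_error(gene_table(data.frame(gene_id = c("a", "a"), chrom = "c",
                                     strand = "+", start = 1, end = 10)),
               "unique")
})

test_that("minimal GTF gene reader extracts gene features", {
  tmp <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("#!genome-build test",
               paste("chr1", "src", "gene", "1001", "2000", ".", "+", ".",
                     'gene_id "gA"; gene_name "A";', sep = "\t"),
               paste("chr1", "src", "exon", "1001", "1200", ".", "+", ".",
                     'gene_id "gA";', sep = "\t")), tmp)
  g <- read_gtf_genes(tmp)
  expect_equal(g$gene_id, "gA")
  expect_equal(g$tss, 1000L)
})

test_that("promoter assignment handles strand orientation as specified", {
  genes <- gene_table(data.frame(
    gene_id = c("plus", "minus"),
    chrom = "chr1", strand = c("+", "-"),
    start = c(10000, 8000), end = c(12000, 10001),
    stringsAsFactors = FALSE), coords = "0-based")
  # tss: plus = 10000; minus = 10000
  peaks <- peak_set(data.frame(
    chrom = "chr1",
    start = c(9400, 10400), end = c(9600, 10600),
    peak_id = c("up_plus", "up_minus"), stringsAsFactors = FALSE))
  asg <- assign_peaks_to_genes(peaks, genes, promoter_window(1000, 0),
                               anchor = "midpoint")
  expect_equal(as.character(asg$category), c("promoter", "promoter"))
  expect_equal(asg$gene_id, c("plus", "minus"))
  expect_equal(asg$tss_distance, c(-500L, -500L))
})

test_that("category precedence, tie-breaking and parameter validation", {
  genes <- gene_table(data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
    start = c(1000, 2000), end = c(5000, 6000),
    stringsAsFactors = FALSE), coords = "0-based")
  # anchor 1600: in gA body and in gB's promoter window -> promoter wins
  p <- peak_set(data.frame(chrom = "chr1", start = 1500, end = 1700,
                           peak_id = "p1"))
  asg <- assign_peaks_to_genes(p, genes, anchor = "midpoint")
  expect_equal(as.character(asg$category), "promoter")
  expect_equal(asg$gene_id, "gB")
  # equidistant promoters tie-break lexicographically
  tie_genes <- gene_table(data.frame(
    gene_id = c("gZ", "gA"), chrom = "chr1", strand = c("+", "-"),
    start = c(2000, 500), end = c(3000, 1001),
    stringsAsFactors = FALSE), coords = "0-based")
  # tss gZ = 2000 (+), gA = 1000 (-); anchor 1500 -> d = -500 for both
  tie_peak <- peak_set(data.frame(chrom = "chr1", start = 1400, end = 1600,
                                  peak_id = "p1"))
  tie <- assign_peaks_to_genes(tie_peak, tie_genes, anchor = "midpoint")
  expect_equal(tie$gene_id, "gA")
  expect_error(assign_peaks_to_genes(p, genes, promoter_window(0, 0)),
               "positive")
  # unknown chromosomes fall through to intergenic
  off <- peak_set(data.frame(chrom = "chrX", start = 1, end = 100,
                             peak_id = "p2"))
  expect_equal(as.character(assign_peaks_to_genes(off, genes)$category),
               "intergenic")
})

test_that("assignment matches the quadratic all-pairs oracle", {
  set.seed(42)
  for (rep in 1:3) {
    genes <- random_genes(50)
    peaks <- random_peaks(300)
    got <- assign_peaks_to_genes(peaks, genes, promoter_window(1000, 0),
                                 anchor = "summit")
    want <- oracle_assign(peaks, genes)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(as.character(got$category), want$category)
    expect_equal(got$tss_distance, want$tss_distance)
  }
})

test_that("assignment is invariant under peak input order", {
  set.seed(7)
  genes <- random_genes(30)
  peaks <- random_peaks(200)
  a <- assign_peaks_to_genes(peaks, genes)
  shuf <- peak_set(peaks[sample(nrow(peaks)), ], "rand")
  b <- assign_peaks_to_genes(shuf, genes)
  b <- b[match(a$peak_id, b$peak_id), ]
  expect_equal(a$gene_id, b$gene_id)
  expect_equal(as.character(a$category), as.character(b$category))
})

test_that("localization summary and TSS profile count correctly", {
  asg <- data.frame(peak_id = sprintf("p%d", 1:4),
                    gene_id = c("a", "b", "c", NA),
                    category = factor(c("promoter", "promoter", "promoter",
                                        "intergenic"),
                                      levels = c("promoter", "gene_body",
                                                 "intergenic")),
                    tss_distance = c(-500L, -500L, 200L, NA))
  ls <- localization_summary(asg)
  expect_equal(ls$fraction[ls$category == "promoter"], 0.75)
  expect_equal(sum(ls$fraction), 1, tolerance = 1e-12)
  expect_error(localization_summary(asg[0, ]), "empty")

  h <- tss_distance_profile(asg, bin_width = 1000)
  expect_equal(h$count[h$bin_start == -1000], 2L)
  expect_equal(h$count[h$bin_start == 0], 1L)
  expect_equal(sum(h$count), 3L)  # mass = gene-assigned peaks
  # zero distance falls in the bin containing 0
  z <- tss_distance_profile(data.frame(tss_distance = 0L), 500)
  expect_equal(z$bin_start, 0L)
  # histogram equals direct counting on a larger random input
  set.seed(11)
  d <- sample(-5000:5000, 1000, replace = TRUE)
  h2 <- tss_distance_profile(data.frame(tss_distance = d), 500)
  direct <- table(floor(d / 500))
  expect_equal(h2$count, as.integer(direct))
  expect_equal(sum(h2$count), 1000L)
})

test_that("peak-set overlap partition matches the quadratic oracle", {
  set.seed(99)
  a <- random_peaks(300, condition = "a")
  b <- random_peaks(300, condition = "b")
  got <- peakset_overlap(a, b, min_overlap_bp = 1)
  want <- oracle_overlap(a, b)
  expect_setequal(got$shared_a$peak_id, a$peak_id[want$shared_a])
  expect_setequal(got$unique_a$peak_id, a$peak_id[!want$shared_a])
  expect_setequal(got$shared_b$peak_id, b$peak_id[want$shared_b])
  expect_equal(got$conserved_fraction_a, mean(want$shared_a))
  # shared + unique partition a
  expect_equal(sort(c(got$shared_a$peak_id, got$unique_a$peak_id)),
               sort(a$peak_id))
  # a larger minimum overlap is stricter
  strict <- peakset_overlap(a, b, min_overlap_bp = 200)
  expect_lte(nrow(strict$shared_a), nrow(got$shared_a))
  want200 <- oracle_overlap(a, b, 200)
  expect_setequal(strict$shared_a$peak_id, a$peak_id[want200$shared_a])
})

test_that("peak-set overlap degenerate cases and validation", {
  set.seed(5)
  a <- random_peaks(40, chroms = "chrA", condition = "a")
  self <- peakset_overlap(a, a)
  expect_equal(self$conserved_fraction_a, 1.0)
  b <- random_peaks(40, chroms = "chrZ", condition = "b")
  expect_equal(peakset_overlap(a, b)$conserved_fraction_a, 0.0)
  expect_error(peakset_overlap(a, b, min_overlap_bp = 0), "min_overlap_bp")
})

test_that("hypergeometric overlap test matches exhaustive enumeration", {
  expect_equal(hypergeometric_overlap_test(0, 4, 5, 10), 1)
  # n_a equals the universe: every draw overlaps completely
  expect_equal(hypergeometric_overlap_test(5, 10, 5, 10), 1)
  expect_equal(hypergeometric_overlap_test(4, 4, 5, 10),
               oracle_hyper(4, 4, 5, 10), tolerance = 1e-12)
  for (k in 0:3)
    expect_equal(hypergeometric_overlap_test(k, 6, 4, 12),
                 oracle_hyper(k, 6, 4, 12), tolerance = 1e-12)
  # monotone non-increasing in k
  p <- vapply(0:4, hypergeometric_overlap_test, 1.0, n_a = 6, n_b = 4,
              universe_n = 12)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(hypergeometric_overlap_test(5, 4, 5, 10), "exceeds")
  expect_error(hypergeometric_overlap_test(1, 11, 5, 10), "universe")
})

test_that("merged-locus universe counts non-overlapping loci", {
  a <- peak_set(data.frame(chrom = "chr1", start = c(0, 50, 500),
                           end = c(100, 150, 600),
                           peak_id = c("a1", "a2", "a3")))
  b <- peak_set(data.frame(chrom = c("chr1", "chr2"),
                           start = c(90, 0), end = c(200, 100),
                           peak_id = c("b1", "b2")))
  expect_equal(peak_universe_size(a, b), 3L)
})
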
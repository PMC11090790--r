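# Cell tables, level classification, group statistics, reconstructions.

make_mini_cells <- function() {
  cell_table(data.frame(
    cell_id = c("c1", "c2", "c3", "c4"),
    x = c(0, 1, 2, 3), y = c(0, 0, 1, 1),
    tissue_class = c("tumor", "tumor", "tumor", "stroma"),
    ZEB1_nuclear = c(2, 7, 25, 1),
    ZEB1_cytoplasmic = 0, ZEB1_membrane = 0,
    NGFR_membrane = c(1, 16, 20, 0),
    NGFR_nuclear = 0, NGFR_cytoplasmic = 0,
    stringsAsFactors = FALSE))
}

test_that("cell table reader validates schema and intensities", {
  cells <- make_mini_cells()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(cells, tmp)
  back <- read_cell_table(tmp)
  expect_equal(back$cell_id, cells$cell_id)
  expect_equal(back$ZEB1_nuclear, cells$ZEB1_nuclear)
  # missing mapped column
  df <- as.data.frame(cells); names(df)[1] <- "id"
  expect_error(cell_table(df), "cell_id")
  # negative intensity
  bad <- as.data.frame(cells); bad$ZEB1_nuclear[1] <- -1
  expect_error(cell_table(bad), "negative")
})

test_that("round-trip write/read identity on a synthetic 100-cell table", {
  cfg <- sim_config(seed = 21, n_cells_spatial = 100)
  sp <- simulate_cell_table(cfg)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(sp$cells, tmp)
  back <- read_cell_table(tmp)
  expect_equal(back$cell_id, sp$cells$cell_id)
  expect_equal(back$tissue_class, sp$cells$tissue_class)
  expect_equal(back$ZEB1_nuclear, sp$cells$ZEB1_nuclear, tolerance = 1e-6)
})

test_that("marker schemes validate their cutoffs", {
  expect_error(marker_scheme("m", c("lo", "hi"), c(1, 2)), "cutoffs")
  expect_error(marker_scheme("m", c("a", "b", "c"), c(2, 1)), "ascending")
  s <- marker_scheme("NGFR", c("not_expressed", "high"), 15, "membrane")
  expect_equal(s$compartment, "membrane")
})

test_that("level classification uses lower-inclusive bins on tumor cells", {
  cells <- make_mini_cells()
  schemes <- list(
    marker_scheme("ZEB1", c("not_expressed", "low", "intermediate", "high"),
                  c(5, 10, 20)),
    marker_scheme("NGFR", c("not_expressed", "high"), 15, "membrane"))
  calls <- classify_marker_levels(cells, schemes)
  expect_equal(nrow(calls), 3)  # stroma cell excluded
  expect_equal(as.character(calls$ZEB1), c("not_expressed", "low", "high"))
  # NGFR two-level vocabulary only
  expect_setequal(levels(calls$NGFR), c("not_expressed", "high"))
  expect_equal(as.character(calls$NGFR), c("not_expressed", "high", "high"))
  # exact cutoff value reaches the upper level (lower-inclusive)
  at_cut <- cells; at_cut$ZEB1_nuclear[1] <- 5
  expect_equal(as.character(classify_marker_levels(at_cut, schemes)$ZEB1)[1],
               "low")
})

test_that("classification matches a per-cell binning oracle and is monotone", {
  cfg <- sim_config(seed = 22, n_cells_spatial = 1000)
  sp <- simulate_cell_table(cfg)
  calls <- classify_marker_levels(sp$cells, sp$schemes)
  s <- sp$schemes$ZEB1
  ints <- sp$cells$ZEB1_nuclear[match(calls$cell_id, sp$cells$cell_id)]
  oracle <- vapply(ints, function(v) {
    lev <- 1L
    for (ct in s$cutoffs) if (v >= ct) lev <- lev + 1L
    s$levels[lev]
  }, "")
  expect_equal(as.character(calls$ZEB1), oracle)
  # monotone: higher intensity never receives a lower level
  ord <- order(ints)
  expect_true(all(diff(as.integer(calls$ZEB1)[ord]) >= 0))
  # per-marker level counts partition the tumor cells
  expect_equal(sum(table(calls$ZEB1)), sum(sp$cells$tissue_class == "tumor"))
  # invariant to row order
  shuf <- sp$cells[sample(nrow(sp$cells)), ]
  calls2 <- classify_marker_levels(cell_table(shuf), sp$schemes)
  calls2 <- calls2[match(calls$cell_id, calls2$cell_id), ]
  expect_equal(as.character(calls$ZEB1), as.character(calls2$ZEB1))
})

test_that("group comparison reports medians and Bonferroni-adjusted p", {
  set.seed(31)
  n <- 60
  cells <- cell_table(data.frame(
    cell_id = sprintf("c%02d", 1:n), x = runif(n), y = runif(n),
    tissue_class = "tumor",
    ZEB1_nuclear = rep(c(2, 25), each = n / 2),
    SOX10_nuclear = c(rnorm(n / 2, 20, 2), rnorm(n / 2, 8, 2)),
    stringsAsFactors = FALSE))
  schemes <- list(
    marker_scheme("ZEB1", c("not_expressed", "low", "intermediate", "high"),
                  c(5, 10, 20)),
    marker_scheme("SOX10", c("not_expressed", "low", "high"), c(8, 16)))
  calls <- classify_marker_levels(cells, schemes)
  cmp <- marker_by_group_comparison(cells, calls, "SOX10", "ZEB1")
  expect_equal(nrow(cmp$tests), 1)   # only two populated groups -> one pair
  expect_equal(cmp$tests$p_adj, pmin(1, cmp$tests$p * 1))
  meds <- setNames(cmp$groups$median, cmp$groups$level)
  expect_gt(meds[["not_expressed"]], meds[["high"]])
  # Bonferroni arithmetic: m tests multiply the raw p
  expect_equal(min(1, 0.01 * 6), 0.06)
})

test_that("Mann-Whitney p matches exact enumeration for small groups", {
  set.seed(37)
  for (rep in 1:5) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    x <- round(runif(n1, 0, 100), 4)   # continuous, no ties
    y <- round(runif(n2, 0, 100), 4)
    got <- suppressWarnings(wilcox.test(x, y, exact = TRUE))$p.value
    expect_equal(got, oracle_wilcox(x, y), tolerance = 1e-12)
  }
  # strict dominance: two-sided p equals twice the single extreme tail
  x <- 101:106; y <- 1:6
  expect_equal(oracle_wilcox(x, y), 2 / choose(12, 6))
  expect_equal(wilcox.test(x, y, exact = TRUE)$p.value, 2 / choose(12, 6))
})

test_that("identical groups rarely reach Bonferroni significance", {
  set.seed(41)
  hits <- 0L
  for (rep in 1:200) {
    x <- rnorm(20); y <- rnorm(20)
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    if (min(1, p * 6) < 0.05) hits <- hits + 1L
  }
  # with 6-fold Bonferroni the family-wise rate is well under 5%
  expect_lte(hits / 200, 0.05)
})

test_that("small groups are excluded with a warning", {
  cells <- make_mini_cells()
  schemes <- list(
    marker_scheme("ZEB1", c("not_expressed", "low", "intermediate", "high"),
                  c(5, 10, 20)),
    marker_scheme("NGFR", c("not_expressed", "high"), 15, "membrane"))
  calls <- classify_marker_levels(cells, schemes)
  # every ZEB1 group has one cell -> no usable pair
  expect_error(suppressWarnings(
    marker_by_group_comparison(cells, calls, "NGFR", "ZEB1")), ">= 2")
})

test_that("co-occurrence table covers the level grid with exact marginals", {
  cfg <- sim_config(seed = 23, n_cells_spatial = 600)
  sp <- simulate_cell_table(cfg)
  calls <- classify_marker_levels(sp$cells, sp$schemes)
  co <- cooccurrence_summary(calls, c("ZEB1", "NGFR", "SOX9"))
  expect_equal(nrow(co), 4 * 2 * 4)        # full Cartesian grid
  expect_equal(sum(co$count), nrow(calls))
  # marginals equal per-marker compositions
  for (m in c("ZEB1", "NGFR", "SOX9")) {
    marg <- tapply(co$count, co[[m]], sum)
    expect_equal(as.integer(marg[levels(calls[[m]])]),
                 as.integer(table(calls[[m]])))
  }
  # single-phenotype input concentrates in one cell of the grid
  one <- calls[rep(1, 5), ]
  co1 <- cooccurrence_summary(one, c("ZEB1", "NGFR"))
  expect_equal(sum(co1$count > 0), 1)
  expect_equal(max(co1$count), 5L)
})

test_that("reconstruction export applies the colour convention", {
  cells <- make_mini_cells()
  schemes <- list(marker_scheme(
    "ZEB1", c("not_expressed", "low", "intermediate", "high"), c(5, 10, 20)))
  calls <- classify_marker_levels(cells, schemes)
  rec <- reconstruction_export(calls, "ZEB1")
  expect_equal(rec$color[rec$level == "high"], "red")
  expect_equal(rec$color[rec$level == "not_expressed"], "grey")
  expect_equal(rec$x, calls$x)
  # round-trip through CSV preserves coordinates and levels
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$level, rec$level)
  expect_equal(back$x, rec$x)
  expect_error(reconstruction_export(calls, "MITF"), "not classified")
  empty <- reconstruction_export(calls[0, ], "ZEB1")
  expect_equal(nrow(empty), 0)
})

test_that("planted ZEB1 / SOX10 antagonism is detected in simulated tumors", {
  cfg <- sim_config(seed = 24, n_cells_spatial = 1000)
  sp <- simulate_cell_table(cfg)
  calls <- classify_marker_levels(sp$cells, sp$schemes)
  cmp <- marker_by_group_comparison(sp$cells, calls, "SOX10", "ZEB1")
  extreme <- cmp$tests[cmp$tests$group1 == "not_expressed" &
                         cmp$tests$group2 == "high", ]
  expect_lt(extreme$p_adj, 0.05)
  meds <- setNames(cmp$groups$median, cmp$groups$level)
  expect_gt(meds[["not_expressed"]], meds[["high"]])
})
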
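# Multiplexed-immunofluorescence single-cell phenotype classification.
#
# Cell tables are CSV with one row per segmented cell: an id, slide
# coordinates, a tissue class (epidermis / stroma / tumor) and per-marker
# mean intensities per cellular compartment, in columns named
# `<MARKER>_<compartment>` (e.g. `ZEB1_nuclear`, `NGFR_membrane`).

TISSUE_CLASSES <- c("epidermis", "stroma", "tumor")
COMPARTMENTS <- c("nuclear", "cytoplasmic", "membrane")

#' Column mapping for cell tables
#'
#' Names the CSV columns holding the cell id, coordinates and tissue
#' class; marker intensity columns are discovered by the
#' `<MARKER>_<compartment>` convention.
#'
#' @param cell_id,x,y,tissue Column names.
#' @return Named list.
#' @export
cell_table_mapping <- function(cell_id = "cell_id", x = "x", y = "y",
                               tissue = "tissue_class") {
  list(cell_id = cell_id, x = x, y = y, tissue = tissue)
}

#' Read a single-cell phenotype table
#'
#' @param path CSV file path.
#' @param mapping A [cell_table_mapping()].
#' @return Data frame with standardized columns `cell_id`, `x`, `y`,
#'   `tissue_class` plus all `<MARKER>_<compartment>` intensity columns,
#'   classed `cell_table`. Non-tumor rows are retained (classification
#'   restricts to tumor later).
#' @export
read_cell_table <- function(path, mapping = cell_table_mapping()) {
  if (!file.exists(path)) stopf("cell table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cell_table(df, mapping)
}

#' @rdname read_cell_table
#' @param cells Data frame of cells.
#' @export
cell_table <- function(cells, mapping = cell_table_mapping()) {
  for (f in names(mapping))
    if (!mapping[[f]] %in% names(cells))
      stopf("cell table is missing mapped column '%s' (for %s)",
            mapping[[f]], f)
  df <- as.data.frame(cells, stringsAsFactors = FALSE)
  names(df)[match(unlist(mapping), names(df))] <-
    c("cell_id", "x", "y", "tissue_class")
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id)) stopf("cell_ids must be unique")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stopf("cell coordinates must be finite")
  if (!all(df$tissue_class %in% TISSUE_CLASSES))
    stopf("tissue_class values must be one of: %s",
          paste(TISSUE_CLASSES, collapse = ", "))
  intensity_cols <- grep(paste0("_(", paste(COMPARTMENTS, collapse = "|"),
                                ")$"), names(df), value = TRUE)
  if (!length(intensity_cols))
    stopf("cell table has no <MARKER>_<compartment> intensity columns")
  for (cc in intensity_cols) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(!is.finite(df[[cc]])) || any(df[[cc]] < 0))
      stopf("negative or non-finite intensity in column '%s'", cc)
  }
  front <- c("cell_id", "x", "y", "tissue_class")
  df <- df[c(front, setdiff(names(df), front))]
  rownames(df) <- NULL
  structure(df, class = c("cell_table", "data.frame"))
}

#' Write a cell table to CSV
#' @param cells A `cell_table`.
#' @param path Output path.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-marker expression-level scheme
#'
#' An ordered level vocabulary for one marker with ascending intensity
#' cutoffs between consecutive levels (one fewer cutoffs than levels) and
#' the cellular compartment whose mean intensity is classified. Bins are
#' lower-inclusive half-open: a cell's level is the highest level whose
#' lower cutoff is `<=` its intensity.
#'
#' @param marker Marker name (e.g. `"ZEB1"`).
#' @param levels Ordered level vocabulary, lowest first (e.g.
#'   `c("not_expressed", "low", "intermediate", "high")`).
#' @param cutoffs Strictly ascending numeric cutoffs,
#'   `length(levels) - 1` of them.
#' @param compartment `"nuclear"`, `"cytoplasmic"` or `"membrane"`.
#' @return List with class `marker_scheme`.
#' @export
marker_scheme <- function(marker, levels, cutoffs,
                          compartment = c("nuclear", "cytoplasmic",
                                          "membrane")) {
  compartment <- match.arg(compartment)
  levels <- as.character(levels)
  cutoffs <- as.numeric(cutoffs)
  if (length(levels) < 2) stopf("a marker scheme needs >= 2 levels")
  if (length(cutoffs) != length(levels) - 1)
    stopf("scheme '%s': need %d cutoffs for %d levels", marker,
          length(levels) - 1, length(levels))
  if (is.unsorted(cutoffs, strictly = TRUE))
    stopf("scheme '%s': cutoffs must be strictly ascending", marker)
  structure(list(marker = as.character(marker), levels = levels,
                 cutoffs = cutoffs, compartment = compartment),
            class = "marker_scheme")
}

#' Default level vocabularies and compartments for the standard panel
#'
#' The conventional six-marker melanoma cell-state panel: ZEB1, ZEB2,
#' MITF and SOX9 carry four levels (not expressed / low / intermediate /
#' high), SOX10 three (not expressed / low / high) and NGFR two (not
#' expressed / high). All markers are classified on nuclear intensity
#' except NGFR (membrane). Cutoffs are data-driven: evenly spaced
#' quantiles of the tumor-cell intensity distribution (0.25/0.5/0.75 for
#' four levels), an explicit synthetic default that must not be mistaken
#' for biologically validated thresholds.
#'
#' @param cells A `cell_table` providing the tumor-cell intensity
#'   distributions.
#' @param markers Markers to build schemes for.
#' @return Named list of [marker_scheme()]s.
#' @export
default_marker_schemes <- function(cells,
                                   markers = c("ZEB1", "ZEB2", "MITF",
                                               "SOX9", "SOX10", "NGFR")) {
  vocab <- function(m)
    switch(m,
           SOX10 = c("not_expressed", "low", "high"),
           NGFR = c("not_expressed", "high"),
           c("not_expressed", "low", "intermediate", "high"))
  comp <- function(m) if (m == "NGFR") "membrane" else "nuclear"
  tumor <- cells[cells$tissue_class == "tumor", , drop = FALSE]
  out <- lapply(markers, function(m) {
    col <- paste0(m, "_", comp(m))
    if (!col %in% names(cells))
      stopf("cell table lacks intensity column '%s'", col)
    lv <- vocab(m)
    qs <- seq_len(length(lv) - 1) / length(lv)
    marker_scheme(m, lv,
                  as.numeric(stats::quantile(tumor[[col]], qs)),
                  compartment = comp(m))
  })
  stats::setNames(out, markers)
}

#' Classify cells into per-marker expression levels
#'
#' Applies each scheme's cutoffs to the corresponding intensity column.
#' Bins are lower-inclusive: intensity `>= cutoffs[i]` reaches at least
#' level `i + 1`. Only cells of the `restrict_to` tissue class are
#' classified.
#'
#' @param cells A `cell_table`.
#' @param schemes List of [marker_scheme()]s.
#' @param restrict_to Tissue class to classify (default `"tumor"`).
#' @return Data frame `cell_id`, `x`, `y`, plus one factor column per
#'   marker with the scheme's ordered levels; classed `level_calls`.
#' @export
classify_marker_levels <- function(cells, schemes, restrict_to = "tumor") {
  if (inherits(schemes, "marker_scheme")) schemes <- list(schemes)
  tumor <- cells[cells$tissue_class %in% restrict_to, , drop = FALSE]
  out <- data.frame(cell_id = tumor$cell_id, x = tumor$x, y = tumor$y,
                    stringsAsFactors = FALSE)
  for (s in schemes) {
    if (!inherits(s, "marker_scheme"))
      s <- do.call(marker_scheme, as.list(s))
    col <- paste0(s$marker, "_", s$compartment)
    if (!col %in% names(tumor))
      stopf("cell table lacks intensity column '%s' for scheme '%s'",
            col, s$marker)
    lev_idx <- findInterval(tumor[[col]], s$cutoffs) + 1L
    out[[s$marker]] <- factor(s$levels[lev_idx], levels = s$levels,
                              ordered = TRUE)
  }
  structure(out, class = c("level_calls", "data.frame"))
}

#' Compare a marker's intensity across groups defined by another marker
#'
#' Cells are grouped by their level call for `group_marker` (e.g. ZEB1
#' high / intermediate / low / not expressed); within each group the
#' intensity of `y_marker` (in its scheme's compartment) is summarised,
#' and all group pairs are compared with a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test. P-values are Bonferroni-corrected:
#' `min(1, m * p)` with `m` the number of pairwise tests actually
#' performed in this call. Groups with fewer than 2 cells are excluded
#' with a warning.
#'
#' @param cells A `cell_table`.
#' @param calls Output of [classify_marker_levels()].
#' @param y_marker Marker whose intensity is compared.
#' @param group_marker Marker whose level calls define the groups.
#' @param y_compartment Compartment of the `y_marker` intensity (defaults
#'   to nuclear, membrane for NGFR).
#' @return List with `groups` (data frame: `level`, `n`, `median`) and
#'   `tests` (data frame: `group1`, `group2`, `statistic`, `p`, `p_adj`).
#' @export
marker_by_group_comparison <- function(cells, calls, y_marker, group_marker,
                                       y_compartment = NULL) {
  if (is.null(y_compartment))
    y_compartment <- if (y_marker == "NGFR") "membrane" else "nuclear"
  ycol <- paste0(y_marker, "_", y_compartment)
  if (!ycol %in% names(cells))
    stopf("cell table lacks intensity column '%s'", ycol)
  if (!group_marker %in% names(calls))
    stopf("no level calls for group marker '%s'", group_marker)
  y <- cells[[ycol]][match(calls$cell_id, cells$cell_id)]
  grp <- calls[[group_marker]]
  keep_levels <- levels(grp)[table(grp)[levels(grp)] >= 2]
  dropped <- setdiff(levels(grp)[table(grp)[levels(grp)] > 0], keep_levels)
  if (length(dropped))
    warnf("excluding group(s) with < 2 cells: %s",
          paste(dropped, collapse = ", "))
  keep_levels <- keep_levels[!is.na(keep_levels)]
  if (length(keep_levels) < 2)
    stopf("need >= 2 groups with >= 2 cells each")
  summ <- data.frame(
    level = keep_levels,
    n = vapply(keep_levels, function(l) sum(grp == l, na.rm = TRUE), 1L),
    median = vapply(keep_levels, function(l)
      stats::median(y[grp == l], na.rm = TRUE), 1.0),
    stringsAsFactors = FALSE)
  pairs <- utils::combn(keep_levels, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    w <- suppressWarnings(
      stats::wilcox.test(y[grp == pr[1]], y[grp == pr[2]],
                         alternative = "two.sided"))
    data.frame(group1 = pr[1], group2 = pr[2],
               statistic = unname(w$statistic), p = w$p.value,
               stringsAsFactors = FALSE)
  }))
  tests$p_adj <- pmin(1, tests$p * nrow(tests))
  list(groups = summ, tests = tests)
}

#' Joint level co-occurrence counts
#'
#' Contingency table over the Cartesian product of the level vocabularies
#' of the selected markers (zero cells included), e.g. to count cells
#' triple-positive for ZEB1, NGFR and SOX9.
#'
#' @param calls Output of [classify_marker_levels()].
#' @param markers Markers to cross-tabulate (all must be classified).
#' @return Data frame with one column per marker plus `count`; counts sum
#'   to the number of classified cells.
#' @export
cooccurrence_summary <- function(calls, markers) {
  miss <- setdiff(markers, names(calls))
  if (length(miss)) stopf("marker(s) not classified: %s",
                          paste(miss, collapse = ", "))
  tab <- as.data.frame(table(calls[markers]), stringsAsFactors = FALSE)
  names(tab) <- c(markers, "count")
  tab$count <- as.integer(tab$count)
  tab
}

#' Level colour convention for spatial reconstructions
#'
#' high = red, intermediate = yellow, low = blue, not expressed = grey.
#'
#' @return Named character vector of colours.
#' @export
level_colors <- function() {
  c(high = "red", intermediate = "yellow", low = "blue",
    not_expressed = "grey")
}

#' Export a whole-slide spatial reconstruction for one marker
#'
#' Per-cell plotting records: coordinates, level call, and the colour code
#' of the convention in [level_colors()]. The output is a plain table any
#' plotting layer can consume (one dot per cell).
#'
#' @param calls Output of [classify_marker_levels()].
#' @param marker Classified marker to export.
#' @return Data frame `cell_id`, `x`, `y`, `level`, `color`.
#' @export
reconstruction_export <- function(calls, marker) {
  if (!marker %in% names(calls))
    stopf("marker '%s' is not classified", marker)
  lev <- as.character(calls[[marker]])
  data.frame(cell_id = calls$cell_id, x = calls$x, y = calls$y,
             level = lev, color = unname(level_colors()[lev]),
             stringsAsFactors = FALSE)
}
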
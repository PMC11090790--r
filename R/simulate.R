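# Synthetic-data generators with ground truth attached.
#
# All generators are pure functions of the configuration: the single
# top-level seed fans out to one fixed-offset substream per generator, so
# adding a generator never perturbs another generator's draws, and an
# identical configuration always yields identical output.

SEED_OFFSETS <- c(peaks = 11L, de = 23L, expr = 37L, cells = 53L,
                  regulon = 71L)

#' Simulation configuration
#'
#' One object holding every knob of the synthetic-data module. Defaults
#' encode the study conditions the generators emulate: a majority
#' (0.62) of binding peaks in strand-oriented promoter windows, a third
#' (0.33) of induced-condition peaks conserved from the basal condition,
#' binding enriched among differentially expressed genes, a small set of
#' true regulon targets among decoys, per-cell regulon activity driving
#' target expression, and a spatial tumor containing a dedifferentiated
#' high-ZEB1 clone with anti-correlated melanocytic markers.
#'
#' @param seed Integer seed (mandatory; every generator derives its own
#'   substream from it).
#' @param n_genes Number of genes in the synthetic annotation.
#' @param n_chroms,chrom_length Synthetic genome shape.
#' @param n_peaks Induced-condition peak count.
#' @param promoter_fraction,gene_body_fraction Peak category mix (the
#'   remainder is intergenic).
#' @param conserved_fraction Fraction of induced peaks also present in the
#'   basal condition.
#' @param basal_fraction Basal peak count as a fraction of `n_peaks`
#'   (the induced condition has about twice as many peaks as basal).
#' @param window [promoter_window()] used when placing promoter peaks.
#' @param de_fraction Baseline probability that a gene is differentially
#'   expressed.
#' @param bound_de_enrichment Odds multiplier applied to the DE
#'   probability of bound genes.
#' @param n_true_targets,n_decoys_bound,n_decoys_de,n_regulon_genes
#'   Regulon-recovery layout: true targets are bound in both contexts and
#'   strongly DE; decoys are bound-only or DE-only.
#' @param n_expr_genes,baseline_mean,baseline_sd,effect_size,noise_sd
#'   Expression model `x = baseline_g + mode_g * effect * theta_j + eps`,
#'   `eps ~ N(0, noise_sd)`; defaults put the activity effect at twice the
#'   noise standard deviation, a moderate signal on a log-like scale.
#' @param n_cells Cells/samples per expression simulation.
#' @param theta_range Range of the uniform per-cell activity draw.
#' @param n_cells_spatial Cells in the spatial tumor simulation.
#' @param triple_positive_fraction Planted fraction of tumor cells
#'   simultaneously high for ZEB1, NGFR and SOX9.
#' @return List with class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 600, n_chroms = 4, chrom_length = 1e7,
                       n_peaks = 500, promoter_fraction = 0.62,
                       gene_body_fraction = 0.19,
                       conserved_fraction = 0.33, basal_fraction = 0.5,
                       window = promoter_window(),
                       de_fraction = 0.25, bound_de_enrichment = 3,
                       n_true_targets = 25, n_decoys_bound = 50,
                       n_decoys_de = 50, n_regulon_genes = 500,
                       n_expr_genes = 500, baseline_mean = 5,
                       baseline_sd = 1, effect_size = 1, noise_sd = 0.5,
                       n_cells = 400, theta_range = c(0, 2),
                       n_cells_spatial = 1000,
                       triple_positive_fraction = 0.05) {
  if (missing(seed)) stopf("sim_config: 'seed' is mandatory")
  assert_scalar_number(seed, "seed")
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_chroms = n_chroms, chrom_length = chrom_length,
              n_peaks = n_peaks, promoter_fraction = promoter_fraction,
              gene_body_fraction = gene_body_fraction,
              conserved_fraction = conserved_fraction,
              basal_fraction = basal_fraction, window = window,
              de_fraction = de_fraction,
              bound_de_enrichment = bound_de_enrichment,
              n_true_targets = n_true_targets,
              n_decoys_bound = n_decoys_bound, n_decoys_de = n_decoys_de,
              n_regulon_genes = n_regulon_genes,
              n_expr_genes = n_expr_genes, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, effect_size = effect_size,
              noise_sd = noise_sd, n_cells = n_cells,
              theta_range = theta_range,
              n_cells_spatial = n_cells_spatial,
              triple_positive_fraction = triple_positive_fraction)
  for (f in c("promoter_fraction", "gene_body_fraction",
              "conserved_fraction", "basal_fraction", "de_fraction",
              "triple_positive_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stopf("sim_config: '%s' must be in [0, 1]", f)
  if (cfg$promoter_fraction + cfg$gene_body_fraction > 1)
    stopf("sim_config: promoter + gene-body fractions exceed 1")
  if (cfg$noise_sd <= 0) stopf("sim_config: noise_sd must be positive")
  # feasibility: genes (with promoter margins) must fit the genome loosely
  if (cfg$n_genes * 30000 > 0.6 * cfg$n_chroms * cfg$chrom_length)
    stopf("sim_config: too many genes for the synthetic genome length")
  structure(cfg, class = "sim_config")
}

sub_seed <- function(config, stream) {
  config$seed + SEED_OFFSETS[[stream]]
}

# ---------------------------------------------------------------------------
# annotation + peaks

#' Simulate a gene annotation and two conditions of binding peaks
#'
#' Genes are placed uniformly on synthetic chromosomes with random
#' strands. Induced-condition peaks receive a category drawn from the
#' configured mix: promoter peaks are anchored inside the strand-oriented
#' promoter window of a gene sampled without replacement, gene-body peaks
#' inside a gene body but outside every promoter window, intergenic peaks
#' away from genes and promoters. Peaks never overlap each other. Each
#' induced peak is conserved (also emitted, with the same coordinates, in
#' the basal condition) independently with probability
#' `conserved_fraction`; the basal condition is padded with basal-only
#' peaks up to `basal_fraction * n_peaks`.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (a [gene_table()]), `peaks` (list of
#'   `basal`/`induced` [peak_set()]s) and `truth` (per-peak categories,
#'   conserved flags and per-condition bound-gene sets).
#' @export
simulate_annotation_and_peaks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(sub_seed(config, "peaks"), {
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    margin <- 30000L
    glen <- sample(2000:20000, config$n_genes, replace = TRUE)
    gchr <- sample(chroms, config$n_genes, replace = TRUE)
    gstart <- vapply(glen, function(l)
      sample.int(config$chrom_length - l - 2L * margin, 1L) + margin, 1L)
    genes <- gene_table(data.frame(
      gene_id = sprintf("g%04d", seq_len(config$n_genes)),
      chrom = gchr,
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      start = gstart, end = gstart + glen,
      stringsAsFactors = FALSE), coords = "0-based")

    up <- config$window$upstream; down <- config$window$downstream
    prom_lo <- ifelse(genes$strand == "+", genes$tss - up,
                      genes$tss - down)
    prom_hi <- ifelse(genes$strand == "+", genes$tss + down,
                      genes$tss + up)

    in_any <- function(chr, pos, lo, hi, chrv) {
      idx <- which(chrv == chr)
      any(pos >= lo[idx] & pos <= hi[idx])
    }

    occupied <- list()  # per chrom: matrix of placed [start, end)
    overlaps_occupied <- function(chr, s, e) {
      occ <- occupied[[chr]]
      !is.null(occ) && any(s < occ[, 2] & e > occ[, 1])
    }
    occupy <- function(chr, s, e) {
      occupied[[chr]] <<- rbind(occupied[[chr]], c(s, e))
    }

    half_widths <- function(n) sample(75:250, n, replace = TRUE)

    place_peaks <- function(categories, id_prefix) {
      n <- length(categories)
      out <- data.frame(chrom = character(n), start = integer(n),
                        end = integer(n),
                        peak_id = sprintf("%s%04d", id_prefix, seq_len(n)),
                        score = round(stats::runif(n, 1, 100), 2),
                        summit = integer(n), category = categories,
                        gene_id = NA_character_, stringsAsFactors = FALSE)
      prom_pool <- sample(seq_len(nrow(genes)))  # promoter genes w/o repl.
      for (i in seq_len(n)) {
        h <- sample(75:250, 1L)
        placed <- FALSE
        for (try in 1:200) {
          if (categories[i] == "promoter") {
            if (!length(prom_pool))
              stopf("simulate_annotation_and_peaks: more promoter peaks than genes")
            g <- prom_pool[1L]
            d <- -sample.int(up - 2L, 1L)  # strictly inside the window
            anchor <- if (genes$strand[g] == "+") genes$tss[g] + d
                      else genes$tss[g] - d
            chr <- genes$chrom[g]; gid <- genes$gene_id[g]
          } else if (categories[i] == "gene_body") {
            g <- sample.int(nrow(genes), 1L)
            anchor <- genes$start[g] +
              sample.int(genes$end[g] - genes$start[g], 1L) - 1L
            chr <- genes$chrom[g]; gid <- genes$gene_id[g]
            if (in_any(chr, anchor, prom_lo, prom_hi, genes$chrom)) next
          } else {
            chr <- sample(chroms, 1L)
            anchor <- sample.int(config$chrom_length - 2L * margin, 1L) +
              margin
            gid <- NA_character_
            if (in_any(chr, anchor, prom_lo, prom_hi, genes$chrom)) next
            if (in_any(chr, anchor, genes$start, genes$end - 1L,
                       genes$chrom)) next
          }
          s <- anchor - h; e <- anchor + h
          if (overlaps_occupied(chr, s, e)) {
            if (categories[i] == "promoter") prom_pool <- prom_pool[-1L]
            next
          }
          occupy(chr, s, e)
          if (categories[i] == "promoter") prom_pool <- prom_pool[-1L]
          out$chrom[i] <- chr; out$start[i] <- s; out$end[i] <- e
          out$summit[i] <- anchor; out$gene_id[i] <- gid
          placed <- TRUE
          break
        }
        if (!placed)
          stopf("simulate_annotation_and_peaks: could not place a %s peak",
                categories[i])
      }
      out
    }

    cat_mix <- c(promoter = config$promoter_fraction,
                 gene_body = config$gene_body_fraction,
                 intergenic = 1 - config$promoter_fraction -
                   config$gene_body_fraction)
    induced_cat <- sample(names(cat_mix), config$n_peaks, replace = TRUE,
                          prob = cat_mix)
    induced <- place_peaks(induced_cat, "ind_")
    conserved <- stats::runif(config$n_peaks) < config$conserved_fraction

    n_basal_extra <- max(0L, round(config$basal_fraction * config$n_peaks) -
                           sum(conserved))
    basal_cat <- sample(names(cat_mix), n_basal_extra, replace = TRUE,
                        prob = cat_mix)
    basal_only <- place_peaks(basal_cat, "bas_")

    basal <- rbind(
      transform(induced[conserved, , drop = FALSE],
                peak_id = sub("^ind_", "con_", peak_id)),
      basal_only)

    truth_peaks <- data.frame(peak_id = induced$peak_id,
                              category = induced$category,
                              gene_id = induced$gene_id,
                              conserved = conserved,
                              stringsAsFactors = FALSE)
    bound_ind <- sort(unique(stats::na.omit(induced$gene_id)))
    bound_bas <- sort(unique(stats::na.omit(basal$gene_id)))
    cols <- c("chrom", "start", "end", "peak_id", "score", "summit")
    list(genes = genes,
         peaks = list(basal = peak_set(basal[cols], "basal"),
                      induced = peak_set(induced[cols], "induced")),
         truth = list(peaks = truth_peaks,
                      bound_basal = bound_bas,
                      bound_induced = bound_ind))
  })
}

# ---------------------------------------------------------------------------
# differential expression

#' Simulate a differential-expression table with binding enrichment
#'
#' Every gene of the annotation is independently differentially expressed
#' with probability `de_fraction`, multiplied (on the odds scale) by
#' `bound_de_enrichment` for genes bound in the induced condition. DE
#' genes receive `|lfc| > 1` (shifted exponential) and very small
#' p-values; non-DE genes receive uniform p-values and `|lfc| < 1`, so the
#' strict threshold filter recovers the planted flags exactly.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element of [simulate_annotation_and_peaks()]
#'   (or any list with `bound_induced` plus a gene universe in
#'   `gene_ids`); alternatively pass `gene_ids` explicitly.
#' @param gene_ids Gene universe (defaults to the bound + unbound genes of
#'   the annotation truth; required when `truth` lacks them).
#' @return List with `de` (the DE table) and `truth` (data frame
#'   `gene_id`, `bound`, `de`, `direction`).
#' @export
simulate_de_table <- function(config, truth, gene_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(gene_ids)) {
    if (!is.null(truth$gene_ids)) gene_ids <- truth$gene_ids
    else stopf("simulate_de_table: supply 'gene_ids' (the gene universe)")
  }
  bound <- gene_ids %in% truth$bound_induced
  withr_seed(sub_seed(config, "de"), {
    n <- length(gene_ids)
    odds0 <- config$de_fraction / (1 - config$de_fraction)
    odds <- ifelse(bound, odds0 * config$bound_de_enrichment, odds0)
    p_de <- odds / (1 + odds)
    de <- stats::runif(n) < p_de
    direction <- ifelse(de, sample(c(1, -1), n, replace = TRUE), 0)
    lfc <- ifelse(de,
                  direction * (1.2 + stats::rexp(n, rate = 1.25)),
                  stats::runif(n, -0.9, 0.9))
    pval <- ifelse(de, 10^(-stats::runif(n, 4, 10)), stats::runif(n))
    list(de = data.frame(gene_id = gene_ids, lfc = lfc, pvalue = pval,
                         stringsAsFactors = FALSE),
         truth = data.frame(gene_id = gene_ids, bound = bound, de = de,
                            direction = direction,
                            stringsAsFactors = FALSE))
  })
}

# ---------------------------------------------------------------------------
# regulon recovery layout

#' Simulate inputs for lineage-regulon recovery
#'
#' A gene universe containing `n_true_targets` true targets (bound in
#' both cellular contexts and strongly differentially expressed),
#' `n_decoys_bound` bound-only decoys (bound in both contexts, not DE),
#' `n_decoys_de` DE-only decoys (strongly DE, bound in at most one
#' context) and inert background genes.
#'
#' @param config A [sim_config()].
#' @return List with `bound_sets` (two contexts), `de` (DE table) and
#'   `truth` (data frame `gene_id`, `role`, `mode`).
#' @export
simulate_regulon_inputs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regulon_genes
  nt <- config$n_true_targets; nb <- config$n_decoys_bound
  nd <- config$n_decoys_de
  if (nt + nb + nd > n)
    stopf("simulate_regulon_inputs: targets + decoys exceed the universe")
  withr_seed(sub_seed(config, "regulon"), {
    ids <- sprintf("t%04d", seq_len(n))
    role <- rep("background", n)
    role[seq_len(nt)] <- "target"
    role[nt + seq_len(nb)] <- "decoy_bound"
    role[nt + nb + seq_len(nd)] <- "decoy_de"
    role <- sample(role)  # scatter roles over the universe
    is_t <- role == "target"; is_b <- role == "decoy_bound"
    is_d <- role == "decoy_de"
    strong_de <- is_t | is_d
    direction <- ifelse(strong_de, sample(c(1, -1), n, replace = TRUE), 0)
    lfc <- ifelse(strong_de,
                  direction * (1.5 + stats::rexp(n, 1)),
                  stats::runif(n, -0.9, 0.9))
    pval <- ifelse(strong_de, 10^(-stats::runif(n, 5, 9)), stats::runif(n))
    de <- data.frame(gene_id = ids, lfc = lfc, pvalue = pval,
                     stringsAsFactors = FALSE)
    # DE-only decoys are bound in context 1 only; bound decoys and true
    # targets in both
    ctx1 <- ids[is_t | is_b | is_d]
    ctx2 <- ids[is_t | is_b]
    list(bound_sets = list(ctx1 = sort(ctx1), ctx2 = sort(ctx2)),
         de = de,
         truth = data.frame(gene_id = ids, role = role,
                            mode = direction, stringsAsFactors = FALSE))
  })
}

# ---------------------------------------------------------------------------
# expression with planted activity

#' Simulate an expression matrix with planted regulon activity
#'
#' `x[g, j] = baseline_g + mode_g * effect_size * theta_j + eps`, with
#' `eps ~ N(0, noise_sd)`; non-target genes have mode 0. `theta` is the
#' planted per-cell activity, drawn uniformly over `theta_range` by
#' default, or supplied explicitly (e.g. two discrete groups).
#'
#' @param config A [sim_config()].
#' @param regulon A [regulon()] whose targets are planted.
#' @param theta Optional numeric vector of per-cell activities.
#' @param n_cells Number of cells (ignored when `theta` is supplied).
#' @return List with `expr` (genes x cells matrix), `theta`, `truth`
#'   (per-gene modes).
#' @export
simulate_expression <- function(config, regulon, theta = NULL,
                                n_cells = config$n_cells) {
  stopifnot(inherits(config, "sim_config"))
  t <- regulon$targets
  if (nrow(t) > config$n_expr_genes)
    stopf("simulate_expression: more targets than expression genes")
  withr_seed(sub_seed(config, "expr"), {
    if (is.null(theta))
      theta <- stats::runif(n_cells, config$theta_range[1],
                            config$theta_range[2])
    n_cells <- length(theta)
    n_bg <- config$n_expr_genes - nrow(t)
    genes <- c(t$gene_id, sprintf("bg%04d", seq_len(n_bg)))
    mode <- c(t$mode, rep(0, n_bg))
    baseline <- stats::rnorm(config$n_expr_genes, config$baseline_mean,
                             config$baseline_sd)
    expr <- baseline +
      outer(mode * config$effect_size, theta) +
      matrix(stats::rnorm(config$n_expr_genes * n_cells,
                          sd = config$noise_sd),
             config$n_expr_genes, n_cells)
    dimnames(expr) <- list(genes, sprintf("cell%04d", seq_len(n_cells)))
    list(expr = expr, theta = theta,
         truth = data.frame(gene_id = genes, mode = mode,
                            stringsAsFactors = FALSE))
  })
}

# ---------------------------------------------------------------------------
# spatial cell tables

SIM_MARKERS <- list(
  ZEB1 = list(levels = 4, cutoffs = c(5, 10, 20), compartment = "nuclear"),
  ZEB2 = list(levels = 4, cutoffs = c(5, 10, 20), compartment = "nuclear"),
  MITF = list(levels = 4, cutoffs = c(5, 10, 20), compartment = "nuclear"),
  SOX9 = list(levels = 4, cutoffs = c(5, 10, 20), compartment = "nuclear"),
  SOX10 = list(levels = 3, cutoffs = c(8, 20), compartment = "nuclear"),
  NGFR = list(levels = 2, cutoffs = 15, compartment = "membrane"))

sim_marker_vocab <- function(nlev) {
  switch(as.character(nlev),
         "4" = c("not_expressed", "low", "intermediate", "high"),
         "3" = c("not_expressed", "low", "high"),
         "2" = c("not_expressed", "high"))
}

#' Fixed marker schemes of the spatial simulator
#'
#' The absolute intensity cutoffs the generator plants its levels
#' against; classifying the simulated table with these schemes recovers
#' the planted levels exactly.
#'
#' @return Named list of [marker_scheme()]s.
#' @export
sim_marker_schemes <- function() {
  out <- lapply(names(SIM_MARKERS), function(m) {
    sp <- SIM_MARKERS[[m]]
    marker_scheme(m, sim_marker_vocab(sp$levels), sp$cutoffs,
                  compartment = sp$compartment)
  })
  stats::setNames(out, names(SIM_MARKERS))
}

# P(marker level | ZEB1 level): columns are the marker's levels, rows the
# four ZEB1 levels. Melanocytic markers (ZEB2 / MITF / SOX10) shift down
# as ZEB1 rises; dedifferentiation markers (SOX9 / NGFR) shift up.
sim_conditional_probs <- function(marker) {
  switch(marker,
    ZEB2 = ,
    MITF = rbind(c(0.05, 0.15, 0.35, 0.45),
                 c(0.10, 0.25, 0.40, 0.25),
                 c(0.30, 0.40, 0.20, 0.10),
                 c(0.60, 0.30, 0.08, 0.02)),
    SOX9 = rbind(c(0.55, 0.30, 0.10, 0.05),
                 c(0.40, 0.35, 0.15, 0.10),
                 c(0.20, 0.30, 0.30, 0.20),
                 c(0.10, 0.20, 0.35, 0.35)),
    SOX10 = rbind(c(0.05, 0.25, 0.70),
                  c(0.10, 0.35, 0.55),
                  c(0.35, 0.45, 0.20),
                  c(0.65, 0.25, 0.10)),
    NGFR = rbind(c(0.97, 0.03),
                 c(0.92, 0.08),
                 c(0.75, 0.25),
                 c(0.55, 0.45)),
    stopf("no conditional table for marker '%s'", marker))
}

sim_intensity_for_level <- function(level_idx, cutoffs) {
  # uniform draw inside the level's intensity bin (top bin: one cutoff
  # width above the last cutoff)
  lo <- c(0, cutoffs)[level_idx]
  hi <- c(cutoffs, cutoffs[length(cutoffs)] * 2)[level_idx]
  stats::runif(length(level_idx), lo, hi - 1e-6)
}

#' Simulate a multiplexed-immunofluorescence cell table
#'
#' Tumor cells are placed in Gaussian blobs around clone centers; the
#' default layout is a melanocytic bulk clone plus a dedifferentiated
#' high-ZEB1 clone. Each tumor cell draws a ZEB1 level from its clone's
#' distribution, then draws every other marker conditionally on that ZEB1
#' level, planting the antagonistic (ZEB2 / MITF / SOX10) and
#' co-expressed (SOX9 / NGFR) structure. A planted fraction of tumor
#' cells is forced triple-positive (ZEB1 / NGFR / SOX9 high); accidental
#' triples outside that draw are demoted so the planted fraction is a
#' clean Bernoulli rate. Intensities are drawn uniformly inside the level
#' bins of [sim_marker_schemes()], so cutoff classification recovers the
#' planted levels exactly. Epidermis and stroma cells are emitted with
#' low background intensities and flagged by tissue class.
#'
#' @param config A [sim_config()].
#' @return List with `cells` (a `cell_table`), `schemes`
#'   ([sim_marker_schemes()]) and `truth` (per-cell clone, planted levels
#'   and triple-positive flag).
#' @export
simulate_cell_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(sub_seed(config, "cells"), {
    n <- config$n_cells_spatial
    n_epi <- round(0.10 * n); n_str <- round(0.15 * n)
    n_tum <- n - n_epi - n_str
    clones <- list(
      bulk = list(center = c(3000, 3000), sd = 700, frac = 0.7,
                  zeb1_probs = c(0.45, 0.35, 0.15, 0.05)),
      zeb1_high = list(center = c(5300, 2500), sd = 450, frac = 0.3,
                       zeb1_probs = c(0.03, 0.07, 0.30, 0.60)))
    clone_id <- sample(names(clones), n_tum, replace = TRUE,
                       prob = vapply(clones, `[[`, 1.0, "frac"))
    xy <- t(vapply(clone_id, function(cl) {
      c(stats::rnorm(1, clones[[cl]]$center[1], clones[[cl]]$sd),
        stats::rnorm(1, clones[[cl]]$center[2], clones[[cl]]$sd))
    }, numeric(2)))
    zeb1_lvl <- vapply(clone_id, function(cl)
      sample.int(4L, 1L, prob = clones[[cl]]$zeb1_probs), 1L)

    lvl <- list(ZEB1 = zeb1_lvl)
    for (m in c("ZEB2", "MITF", "SOX9", "SOX10", "NGFR")) {
      pr <- sim_conditional_probs(m)
      lvl[[m]] <- vapply(zeb1_lvl, function(z)
        sample.int(ncol(pr), 1L, prob = pr[z, ]), 1L)
    }
    # plant the triple-positive rate: forced triples in, accidental out
    forced <- stats::runif(n_tum) < config$triple_positive_fraction
    lvl$ZEB1[forced] <- 4L; lvl$NGFR[forced] <- 2L; lvl$SOX9[forced] <- 4L
    accidental <- !forced & lvl$ZEB1 == 4L & lvl$NGFR == 2L &
      lvl$SOX9 == 4L
    lvl$SOX9[accidental] <- 3L

    tumor <- data.frame(cell_id = sprintf("tum%05d", seq_len(n_tum)),
                        x = xy[, 1], y = xy[, 2],
                        tissue_class = "tumor", stringsAsFactors = FALSE)
    non_tumor <- data.frame(
      cell_id = c(sprintf("epi%05d", seq_len(n_epi)),
                  sprintf("str%05d", seq_len(n_str))),
      x = stats::runif(n_epi + n_str, 0, 8000),
      y = c(stats::runif(n_epi, 7000, 8000),
            stats::runif(n_str, 0, 7000)),
      tissue_class = rep(c("epidermis", "stroma"), c(n_epi, n_str)),
      stringsAsFactors = FALSE)
    cells <- rbind(tumor, non_tumor)

    for (m in names(SIM_MARKERS)) {
      sp <- SIM_MARKERS[[m]]
      main_col <- paste0(m, "_", sp$compartment)
      vals <- c(sim_intensity_for_level(lvl[[m]], sp$cutoffs),
                stats::runif(n_epi + n_str, 0, 4))  # background, non-tumor
      cells[[main_col]] <- vals
      for (other in setdiff(COMPARTMENTS, sp$compartment))
        cells[[paste0(m, "_", other)]] <- stats::runif(n, 0, 3)
    }

    vocabs <- lapply(names(SIM_MARKERS), function(m)
      sim_marker_vocab(SIM_MARKERS[[m]]$levels))
    names(vocabs) <- names(SIM_MARKERS)
    planted <- data.frame(cell_id = tumor$cell_id, clone = clone_id,
                          triple_positive = forced,
                          stringsAsFactors = FALSE)
    for (m in names(lvl)) planted[[m]] <- vocabs[[m]][lvl[[m]]]

    list(cells = cell_table(cells), schemes = sim_marker_schemes(),
         truth = planted)
  })
}

# ---------------------------------------------------------------------------
# signatures + one-call emitter

#' Simulate gene signatures with planted binding coverage
#'
#' Signatures drawn from the annotation's gene universe with controlled
#' fractions of bound genes, for exercising binding-coverage summaries.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element of [simulate_annotation_and_peaks()].
#' @param coverages Named numeric vector: planted bound fraction per
#'   signature.
#' @param size Genes per signature.
#' @return Named list of [gene_signature()]s.
#' @export
simulate_signatures <- function(config, truth,
                                coverages = c(proliferative = 0.4,
                                              invasive = 0.45,
                                              transitory = 0.2),
                                size = 40) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(sub_seed(config, "regulon") + 1L, {
    bound <- truth$bound_induced
    unbound <- setdiff(truth$gene_ids, bound)
    sigs <- lapply(names(coverages), function(nm) {
      nb <- round(coverages[[nm]] * size)
      gene_signature(nm, c(sample(bound, nb),
                           sample(unbound, size - nb)))
    })
    stats::setNames(sigs, names(coverages))
  })
}

#' Emit every synthetic input to a directory
#'
#' Runs all generators under one configuration and writes
#' `genes.tsv`, `peaks_basal.bed`, `peaks_induced.bed`, `de.tsv`,
#' `sets.gmt`, `regulon.tsv`, `expr.tsv`, `cells.csv` and `truth.json`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_all <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation_and_peaks(config)
  ann$truth$gene_ids <- ann$genes$gene_id
  de <- simulate_de_table(config, ann$truth)
  sigs <- simulate_signatures(config, ann$truth)
  reg_in <- simulate_regulon_inputs(config)
  reg <- build_lineage_regulon(reg_in$bound_sets, reg_in$de,
                               tf_name = "TF_sim")
  ex <- simulate_expression(config, reg)
  sp <- simulate_cell_table(config)

  write_gene_table(ann$genes, file.path(outdir, "genes.tsv"))
  write_bed(ann$peaks$basal, file.path(outdir, "peaks_basal.bed"))
  write_bed(ann$peaks$induced, file.path(outdir, "peaks_induced.bed"))
  utils::write.table(de$de, file.path(outdir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(sigs, file.path(outdir, "sets.gmt"))
  write_regulon(reg, file.path(outdir, "regulon.tsv"))
  write_expression_tsv(round(ex$expr, 4), file.path(outdir, "expr.tsv"))
  write_cell_table(sp$cells, file.path(outdir, "cells.csv"))
  truth <- list(peaks = ann$truth$peaks,
                bound_basal = ann$truth$bound_basal,
                bound_induced = ann$truth$bound_induced,
                de = de$truth, regulon = reg_in$truth,
                theta = ex$theta, cells = sp$truth)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(list(annotation = ann, de = de, signatures = sigs,
                 regulon_inputs = reg_in, regulon = reg,
                 expression = ex, cells = sp))
}
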
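# regulonkit

Tools for characterising the direct transcriptional program of a
transcription factor (TF) from ChIP-seq binding and expression data, and
for scoring that program's activity in bulk, single-cell and spatial
single-cell data.

The package grew out of a concrete problem in melanoma biology. Melanoma
cells switch reversibly between a proliferative/differentiated state
(MITF-high, SOX10-high) and invasive or neural-crest-stem-cell-like
states (NGFR/SOX9-high), and the EMT factor ZEB1 is a central regulator
of these transitions. Characterising such a regulator requires a chain of
analyses that recur across any TF study in any lineage:

1. **Peak annotation** — assign ChIP-seq peaks to genes through
   strand-oriented promoter windows around the transcription start site
   (TSS), summarise peak localization and TSS-distance profiles, and
   compare peak sets between conditions with hypergeometric
   significance.
2. **Binding x expression integration** — filter differential-expression
   (DE) tables at strict thresholds (`p < 0.001`, `|log2 FC| > 1` by
   default), report the fraction of bound genes among up-, down- and all
   DE genes with enrichment tests, and classify per-gene binding
   dynamics (conserved / de novo / lost) between conditions.
3. **Signatures** — GMT I/O, per-signature binding coverage, and
   single-sample gene-set enrichment (ssGSEA, Barbie-style weighted
   running sum).
4. **Regulon construction** — build a lineage-specific signed regulon by
   intersecting the genes bound in two (or more) cellular contexts with
   strongly DE genes; the regulation mode is `sign(lfc) x tf_direction`.
5. **TF activity** — a self-contained, two-tailed weighted enrichment
   statistic over rank signatures with an aREA-style analytic
   normalisation (`NES = ES * sum(w) / sqrt(sum(w^2))`) and a seeded
   permutation null, applied per contrast or per cell.
6. **Spatial phenotyping** — cutoff-based classification of multiplexed
   immunofluorescence cell tables into per-marker expression levels,
   Mann-Whitney/Bonferroni group comparisons, co-occurrence counts and
   whole-slide dot-map exports.
7. **Synthetic data** — seeded generators producing every input above
   with ground truth attached (planted promoter fractions, conserved
   binding, DE enrichment, regulon targets, per-cell activity, clonal
   marker co-expression), so the whole chain is testable without any
   external download.

## The core statistic

For a regulon with targets `g`, modes `m_g` (+1 activated / -1
repressed) and weights `w_g`, and a rank signature assigning each gene
the standard-normal quantile `z_g` of its midrank,

```
ES  = sum_g m_g w_g z_g / sum_g w_g
NES = ES * sum_g w_g / sqrt(sum_g w_g^2)
```

The analytic NES is exact when the `z_g` are standard-normal quantiles;
a seeded permutation null (`(ES - mean) / sd` over gene-label
permutations) is provided as ground truth and agrees with the analytic
form within Monte-Carlo error.

## Worked example

```r
library(regulonkit)

cfg <- sim_config(seed = 42)

## ChIP geometry: localization and condition overlap
ann <- simulate_annotation_and_peaks(cfg)
asg <- assign_peaks_to_genes(ann$peaks$induced, ann$genes)
localization_summary(asg)
#>     category count fraction
#> 1   promoter   318    0.636
#> 2  gene_body    80    0.160
#> 3 intergenic   102    0.204
peakset_overlap(ann$peaks$induced, ann$peaks$basal)$conserved_fraction_a
#> [1] 0.33

## binding x differential expression
ann$truth$gene_ids <- ann$genes$gene_id
de  <- simulate_de_table(cfg, ann$truth)
sel <- select_de_genes(de$de)
bound_fraction_report(sel$up, sel$down, ann$truth$bound_induced,
                      ann$genes$gene_id)
#>        class   n n_bound  fraction     p_enrich
#> 1     all_de 241     168 0.6970954 1.675224e-06
#> 2         up 120      90 0.7500000 1.551068e-05
#> 3       down 121      78 0.6446281 7.037781e-02
#> 4 background 359     181 0.5041783 9.999993e-01

## lineage regulon and per-cell activity
ri  <- simulate_regulon_inputs(cfg)
reg <- build_lineage_regulon(ri$bound_sets, ri$de, tf_name = "ZEB1.mel")
reg
#> regulon 'ZEB1.mel': 25 targets (10 activated, 15 repressed)
ex <- simulate_expression(cfg, reg, n_cells = 100)
am <- activity_matrix(ex$expr, reg)
cor(am[1, ], ex$theta, method = "spearman")
#> [1] 0.982
```

The localization table says 63.6% of the 500 induced-condition peaks
fall in promoter windows (the generator plants 62%); a third of induced
peaks are conserved from the basal condition; bound genes are clearly
enriched among DE genes; the 25 planted regulon targets are recovered
exactly; and the per-cell NES tracks the planted activity with Spearman
correlation 0.98.

A command-line dispatcher over the same functions is installed at
`inst/cli/regulonkit.R` (subcommands `annotate-peaks`, `overlap`,
`integrate`, `ssgsea`, `build-regulon`, `score-activity`,
`classify-cells`, `simulate`).

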
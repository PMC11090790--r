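---
title: "Methods: promoter annotation, regulon construction and activity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter annotation, regulon construction and activity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonkit)
```

This vignette is the package's own account of its methods: the models
and conventions behind each stage, the parameters that matter, the
numerical choices made where the design was genuinely open, and what the
synthetic-data generators do and do not establish about real data.

## Coordinate conventions

Two conventions coexist in genomics files and silently corrupt analyses
when mixed. The package pins them at the readers:

* peaks (BED) are **0-based half-open** `[start, end)`;
* gene tables on disk are **1-based inclusive** and converted on read;
  the stored TSS is the 0-based coordinate of the first transcribed base
  (`start` on `+`, `end - 1` on `-`).

## Promoter assignment

A peak is reduced to an anchor point: its summit when one was recorded,
otherwise its interval midpoint (`anchor = "midpoint"` forces the
midpoint). Whether a full-width peak or its summit should decide
promoter membership is not settled usage; the summit-first default
reflects that a point-source binding model is the natural reading for a
sequence-specific TF, and the choice is exposed.

The promoter of a gene is the **strand-oriented closed window**
`[-upstream, +downstream]` of oriented TSS distances, default
`(1000, 0)`: one kilobase upstream through the TSS itself, in the gene's
transcriptional direction. Oriented distance is `pos - tss` on `+`
genes and `tss - pos` on `-` genes, so negative always means upstream.
We chose the closed interval at both ends; with integer coordinates the
choice only moves single-base boundary cases, and the synthetic
generator places promoter anchors strictly inside the window so its
ground truth is insensitive to it.

Each peak receives exactly one category with fixed precedence:
**promoter** beats **gene body** beats **intergenic**. Among several
eligible genes the smallest `|oriented distance|` wins and remaining
ties break lexicographically on `gene_id`, so assignment is
deterministic and invariant to input order — both properties are tested,
and the whole operation is checked against a quadratic all-pairs oracle.
Interval queries go through `GenomicRanges`/`IRanges`; the category and
tie-break logic is the package's own.

## Peak-set comparison

Two peak sets are compared by partitioning each into shared and unique
peaks; a peak is shared when it overlaps any peak of the other set by at
least `min_overlap_bp` (default 1 bp — the permissive convention for
Venn-style figures; raise it for stricter reciprocal support).
Significance of an overlap uses the upper-tail hypergeometric
probability. The default universe for peak-level Venn tests is the
pooled peaks merged into non-overlapping loci (`peak_universe_size`);
no universe is canonical, and the choice matters, so it is an explicit
argument. For gene-level Venns the annotated gene universe is the
natural choice. Note one degenerate regime: when shared peaks have
byte-identical coordinates (as in the synthetic generator), the merged
universe makes the margins force the observed overlap and the test is
uninformative by construction; the acceptance script therefore reports
the bound-gene Venn against the gene universe.

## Differential expression semantics

`select_de_genes` uses **strict** inequalities: `p < p_max` and
`|lfc| > lfc_min`, defaults `0.001` and `1` (log2 units). Boundary rows
(`p == 0.001`, `|lfc| == 1`) are excluded — tested explicitly, since
off-by-one-row differences here propagate into every downstream gene
set. Filtering is on the raw p-value column by default with
`use_padj = TRUE` as the alternative; fold-changes are assumed log2.

## Regulon construction

`build_lineage_regulon` implements intersection-and-filter: candidate
targets are the genes bound in *every* supplied cellular context;
targets are the candidates passing the DE filter. The mode is
`sign(lfc) * tf_direction`, where `tf_direction = +1` declares that the
contrast raises TF activity (an induction experiment) and `-1` a
knock-down. "Highly differentially expressed" is not a quantified
notion; the regulon reuses the DE filter defaults above as the only
principled thresholds available, configurable. Weights default to a
uniform 1 — no confidence model is imposed — with `weight_mode =
"pvalue"` (weight `1 - p`) as an option. An empty result is an error,
never a silently empty regulon.

## Rank signatures and the enrichment statistic

Two signature constructions are provided:

* `signed_stat` for contrasts: `sign(lfc) * (-log10 p)`, capped at
  ±10 so `p = 0` cannot inject infinities;
* `percell_rank` for single profiles: the midrank quantile
  `qnorm((r - 0.5) / n)`, which maps the median gene of an odd profile
  to exactly 0 and makes scoring invariant under any strictly monotone
  transform of expression.

The regulon enrichment score is the weighted mean of target z-scores
with repressed targets sign-flipped (two-tailed). The analytic NES
multiplies by `sum(w) / sqrt(sum(w^2))`, the exact standardisation when
z-scores are independent standard normals; midrank quantiles are a
finite population sampled without replacement, so the null standard
deviation sits slightly below 1 (the calibration test brackets it in
`[0.9, 1.1]` over 2000 null draws at a 1000-gene namespace, 20
targets). The permutation null permutes gene labels within the
signature namespace under a caller-supplied seed and is the ground
truth the analytic form is verified against (agreement within 3x
Monte-Carlo standard error at 10,000 permutations). Three-tailed or
pleiotropy corrections found in full VIPER are deliberately not
implemented; this is a self-contained two-tailed statistic, and
cross-package numeric agreement is not a goal.

Degenerate inputs error loudly: constant profiles (all ties) warn and
return an all-zero signature; a regulon with no target in the namespace
is an error; a permutation null with zero variance (regulon covering
the namespace) is an error.

## ssGSEA

The single-sample score is the Barbie-style running sum: genes ordered
by decreasing midrank (ties in the ordering broken by gene id for
determinism), in-set genes accumulating weight `|rank|^alpha`, out-set
genes accumulating `1 / (n - k)`, and the score summing the difference
over all positions. `alpha` defaults to 0.25, the commonly published
default; no cross-sample normalisation is applied unless
`normalization = "global_range"` is requested, and scores are only
comparable within one parameterisation. Signature genes absent from the
profile are dropped (logged when `verbose`). The implementation is
tested for exact equality (1e-12) against an independent re-derivation
of the running sum and for monotone-transform invariance.

## Spatial phenotyping

Cell tables carry per-cell coordinates, a tissue class and
per-marker/per-compartment mean intensities. Classification applies
per-marker schemes: an ordered level vocabulary (four levels for
ZEB1/ZEB2/MITF/SOX9, three for SOX10, two for NGFR) with strictly
ascending cutoffs, **lower-inclusive half-open** bins, restricted to
tumor cells. Real cutoffs are instrument- and panel-specific and are
therefore mandatory configuration; `default_marker_schemes` derives
evenly spaced quantile cutoffs (0.25/0.5/0.75 of tumor intensity for
four levels) as an explicitly synthetic default. Compartments follow
antibody localisation convention: nuclear for the transcription
factors, membrane for NGFR.

Group comparisons use the two-sided Mann-Whitney test
(`stats::wilcox.test`, exact for small untied groups, verified against
full enumeration for group sizes <= 8) with Bonferroni correction
`min(1, m p)`, where the family `m` is the set of pairwise tests
performed in that call; groups with fewer than two cells are dropped
with a warning. Reconstructions export one record per cell with the
colour convention high = red, intermediate = yellow, low = blue,
not expressed = grey.

## The synthetic-data module

Generators are pure functions of a `sim_config`: one top-level seed
fans out to fixed-offset substreams per generator, so outputs are
byte-reproducible and adding a generator does not disturb the others.
Defaults encode the study conditions the package is exercised under —
62% of peaks in promoter windows, 33% of induced peaks conserved from
the basal condition, a basal set about half the size of the induced
set, binding multiplying DE odds threefold, 25 true regulon targets
among bound-only and DE-only decoys, and a 5% triple-positive
(ZEB1/NGFR/SOX9-high) cell fraction inside a tumor containing a
dedifferentiated high-ZEB1 clone.

Scales were chosen for routine desk runs and are stated here as the
package's own choice: a 4 x 10 Mb genome with 600 genes and 500
induced peaks; 500-gene expression universes; 400-cell activity
simulations; 1000-cell spatial tables. Peaks are placed without mutual
overlap, promoter anchors strictly inside windows and at most one
promoter peak per gene, so planted categories are recovered exactly up
to rare boundary effects (the self-consistency test requires >= 99%
agreement and near-exact bound-gene recovery).

The expression model is `x = baseline_g + mode_g * effect * theta_j +
noise`, Gaussian on a log-like scale with `effect = 1` and `noise_sd =
0.5` — a moderate effect twice the noise — and gene baselines
`N(5, 1)`. One consequence worth knowing: with activity fixed at zero,
the fixed baseline ordering still contributes a constant per-regulon
NES offset shared by all cells (a single draw from the null), so the
null-centred check flattens baselines; across cells the *variation* in
NES is what tracks planted activity. Spatial intensities are drawn
uniformly within the level bins of fixed synthetic cutoffs, with all
other markers drawn conditionally on the planted ZEB1 level — a
monotone-decreasing table for ZEB2/MITF/SOX10 and increasing for
SOX9/NGFR — which plants the antagonism the group statistics are asked
to detect.

What passing these tests shows is that the algorithms are correct on
data satisfying their assumptions, with known answers. What they do not
show: robustness to peak-caller artefacts, mappability and copy-number
biases, dropout and depth variation in single-cell counts, segmentation
errors or slide-to-slide intensity shifts in imaging data. None of
those processes is modelled.

## Known limitations

* Peak calling, alignment and expression quantification are upstream;
  the package starts at called peaks and DE tables.
* Localization uses three categories (promoter / gene body /
  intergenic); finer genomic classes (exon, intron, UTR) are not
  distinguished.
* The activity statistic is two-tailed aREA-style only; no multi-sample
  inference.
* Regulon weights carry no likelihood model beyond the optional
  `1 - p`.
* Cross-slide intensity normalisation for imaging panels is the user's
  responsibility; cutoffs are configuration, not biology.
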
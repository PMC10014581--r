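---
title: "Models and methods behind atacdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atacdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdyn)
```

`atacdyn` implements a regulatory-genomics workflow for staged
differentiation time courses: from ATAC-seq peak intervals to named
temporal enhancer classes, enhancer-gene links, enrichment statistics
against gene sets and tissue H3K27ac enhancer catalogues, and bootstrap
alignment of single-cell RNA-seq clusters between datasets. This vignette
documents the statistical models, the default parameter values and why they
were chosen, the synthetic generators used for validation, and the known
limitations.

## The scientific setting

A directed-differentiation time course (here the default stage order is
ESC, ADE, VFGp3, VFGp6, PE — embryonic stem cells through anterior
definitive endoderm and ventral foregut expansion to pancreatic endoderm)
is profiled by ATAC-seq at every stage with replicates. The questions the
package answers:

1. Which accessible regions (peaks) change over the time course, and what
   temporal shape do they follow?
2. Which genes do the dynamic enhancers plausibly regulate, and are
   enhancer classes over-represented near up- or down-regulated genes?
3. Do the enhancer classes coincide with enhancers active in adult
   tissues of matching or mismatching germ-layer origin (H3K27ac sets)?
4. Do cell clusters from two single-cell RNA-seq datasets (e.g. two
   differentiation protocols, or in vitro versus in vivo) correspond?

## Interval algebra

BED conventions throughout: 0-based, half-open `[start, end)` intervals.
`intersect_atlas()` reproduces the classic overlap filters: "report each
a-interval at most once if some b-interval overlaps it by at least a
fraction f of its length" (optionally reciprocally), and the complement
("no overlap at all"). `reproducible_peaks()` is the 50% reciprocal
replicate filter; `consensus_atlas()` concatenates, sorts and merges to
build the peak universe.

A deliberate numerical choice: fraction thresholds are tested in
scaled-integer arithmetic (`overlap_bp * 10^6 >= round(f * 10^6) * len_bp`)
so boundary cases — a 50 bp overlap of a 100 bp peak at f = 0.5 — are exact
and never depend on floating-point rounding. The test suite validates all
modes against brute-force all-pairs oracles on hundreds of random
instances.

`tn5_shift()` moves raw read 5' ends to Tn5 insertion centres (+4 bp on
`+`, −5 bp on `-` strands; negative results clip to 0 with a count), and
`insertion_coverage()` accumulates 30 bp insertion-centred fragments into
run-length bedGraph coverage with an exact breakpoint sweep.

## Dynamic peaks: negative-binomial GLM

Counts of insertions in peak `i`, sample `j` are modelled as
NB(mu_ij, alpha_i) with `log mu_ij = x_j' b_i + log N_j`, where `x_j`
codes the stage factor and `N_j` is the library size. The stage factor is
tested against the intercept-only model by likelihood ratio
(chi-squared, stages − 1 df). A peak is *dynamic* when its largest
absolute stage-versus-first-stage log2 fold change exceeds 2 **and** its
Benjamini–Hochberg adjusted p-value is below 0.005, both strict. The
fitting engine is edgeR's `glmFit`/`glmLRT`, the field-standard
implementation of exactly this model.

**Dispersion.** Two estimators are offered.

* `dispersion = "eb"` (default): edgeR's empirical-Bayes tagwise estimate,
  which shares information across peaks. With only two replicates per
  stage a raw per-peak estimate is extremely noisy, and in null
  simulations (2,000 flat NB peaks, dispersion 0.1, five stages, two
  replicates) the raw method-of-moments estimator produced an
  anti-conservative test (p < 0.05 rate ≈ 0.12). The empirical-Bayes
  default restores calibration (≈ 0.05, inside [0.03, 0.07]) with zero
  false calls at the strict dynamic thresholds.
* `dispersion = "mom"`: the simple per-peak method-of-moments estimate,
  floored at 0.01 and shrunk 50% toward the global median. Retained
  because it is transparent and assumption-light, and cross-checked in the
  tests against per-peak `MASS::negative.binomial` GLM fits (agreement to
  ~1e-10 in p-values), but not recommended at small replicate numbers for
  the reason above.

A `method = "gaussian"` fallback (one-way F-test on `log2(RPKM + 1)`) is
provided for quick sanity checks; it is validated against `stats::lm`
ANOVA in the tests.

## Temporal classification: fuzzy c-means and archetype naming

Dynamic-peak trajectories are replicate-averaged `log2(RPKM + 1)` stage
means, z-scored per peak (`standardize_trajectories()`), then clustered
with fuzzy c-means (`cmeans_cluster()`): k = 8 clusters, fuzzifier
m = 1.25, Euclidean distance. The low fuzzifier suits z-scored trajectory
data, where cluster overlap is high and a large m collapses memberships
toward uniformity. The implementation is in-package because the per-
iteration objective trace and deterministic seeding are part of the
contract (the objective `sum u^m d^2` is asserted non-increasing in the
tests, and the partition is cross-checked against `e1071::cmeans` on
separated data).

The eight clusters are then merged onto six named groups by correlating
each centroid with a library of canonical temporal archetypes
(`enhancer_archetypes()`), taking the best Pearson match:

* `ADE^OFF` — open in ESC, decommissioned upon ADE induction;
* `VFG^OFF` — opened at ADE, decommissioned during VFG expansion;
* `PE^OFF` — open through foregut stages, closed at PE;
* `PE^ON` — opened only at PE;
* `VFG^TR` — transiently open during VFG expansion;
* `PE^PRIMED` — progressively opening toward PE.

Several centroids may map to one archetype (the 8-to-6 merge); correlation
ties break deterministically by library order with a warning. Choosing
k larger than the number of named groups lets the clustering absorb shape
variants before naming, rather than forcing six clusters directly.

`pairwise_open_close()` complements the global clustering with
transition-specific classes: over the two expansion-stage transitions,
peaks that gain accessibility (|log2FC| > 2, BH p < 0.005 per two-stage NB
test) without having been open earlier are `<stage>^OPEN`; peaks open at
the preceding stage that lose accessibility are `<stage>^CLOSE`. "Open at
a stage" means the replicate-averaged `log2(RPKM+1)` exceeds the midpoint
of the peak's own range — a scale-free criterion under which flat peaks
are never "open". First-match assignment keeps classes disjoint.
`cross_protocol_classes()` intersects the pancreas-directed classes with
an external protocol's stage peak sets (PP1, DE), producing the
`PE-PP1-common`, `PE-not-PP1`, `VFG^OFF-in-DE-PP1` and `VFG^TR-in-PP1`
sets.

## Enhancer-gene links and enrichment

`nearest_tss_assignment()` assigns each peak to the single nearest TSS by
midpoint distance, unstranded, within a window (25 kb for conservative,
200 kb for permissive linking); equidistant ties resolve to the
lexicographically smaller gene id, with a warning, so results are
reproducible. Promoter-proximal peaks (midpoint within 2 kb of any TSS)
are removed before temporal clustering (`filter_promoter_distal()`).

Differential-expression gene sets are thresholded with
`filter_de_genes()`: baseMean > 1,000, |log2FC| > 1.5, adjusted p < 0.05,
all strict, split by direction.

Enrichment of a class in a gene or region set
(`class_geneset_enrichment()`, `class_region_enrichment()`) is scored as
`log2(observed / expected)` with `expected = n_class * K / N` — the
two-way contingency expectation, where K is the number of universe
elements in the set and N the universe size. Significance comes from the
1-df chi-squared test on the implied 2×2 table without continuity
correction. The universe is the set of links whose peak carries a class
label: the table contrasts one class against the other classes, so links
from unclassified peaks (static peaks, when the link table covers the
whole atlas) are excluded before any total is formed — keeping them would
dilute the expected in-set rate with peaks that were never candidates for
any class (checked against `stats::chisq.test(correct = FALSE)` and a
hand-computed case: table [[10, 90], [20, 80]] gives chi-squared 3.9216
and score log2(10/15) = −0.585). `observed = 0` yields a −Inf score
flagged `censored`; an empty expectation yields an all-NA row rather than
an error. An optional label-permutation p-value is available when the
chi-squared approximation is in doubt.

`build_tissue_sets()` prepares tissue H3K27ac catalogues: replicate-
consistent regions (50% reciprocal overlap), tissue-unique regions (no
overlap in any other tissue), and lineage-unique sets pooled per germ
layer — the inputs for class-versus-tissue enrichment.

## Cluster alignment between single-cell datasets

Cells pass QC with UMIs strictly inside (2,000, 35,000), detected genes
strictly inside (550, 4,950), and mitochondrial fraction at most 20%.
Expression is log-normalized (`ln(1 + 10^4 * count / total)`), genes are
z-scored to remove per-gene platform scale, and the comparison panel is
the union of each dataset's top 2,000 highly variable genes restricted to
shared genes.

`bootstrap_cluster_profiles()` resamples each cluster's cells with
replacement `n_boot = 1000` times, recording the panel-mean expression of
each resample; each cluster draws from its own RNG stream derived from the
seed and the cluster label, so profiles are reproducible and independent
of cluster order. `align_clusters()` computes, for each query cluster, the
Euclidean distance from every bootstrap replicate to each target cluster's
bootstrap centroid, ranks targets by mean distance, and declares a
significant alignment to the top r targets (r up to `rank_depth = 2`) when
the rank-r distances are smaller than `(1 − effect_margin)` times the
rank-(r+1) distances by a one-sided Welch test at `alpha = 0.01`.

The significance criterion combines a **relative** and an **absolute**
condition, the package's resolution of an otherwise under-specified
decision.

The relative condition is the margin (default 0.1). A pure
nearest-versus-second-nearest gap test is degenerate: with hundreds of
bootstrap replicates, *any* two unequal mean distances separate
significantly, so a cluster with no true partner — far from every target,
but trivially nearer to one of them — would be called aligned. Requiring
the nearest target to be at least 10% closer than the runner-up is
scale-free (distances grow with panel size) and separates shared
signatures (which sit at roughly half the runner-up distance) from
partnerless clusters (within ~2% of it).

Relative separation alone is still insufficient on the escalation path:
a partnerless cluster can be genuinely *relatively* closer to one subset
of wrong targets than to another (its top two wrong targets jointly
separate from the rest), which would align it to both under `rank_depth`.
The absolute condition closes this: a significant pair must also have a
Pearson correlation of at least `min_cor` (default 0.5 — the pair must
share the majority of its standardized profile structure) between the
query and target centroid profiles across the gene panel. Genuine matches
correlate strongly (~0.8 in the planted simulations), while clusters
without a partner correlate near zero or negatively with every target, so
neither cutoff is finely balanced. The criterion parameters are recorded
in the result's metadata (`glance()`).

## Synthetic data with planted ground truth

Every pipeline input can be generated by `sim_config()` +
`simulate_workspace()`, with defaults that emulate the study conditions:

* five stages × two replicates, library sizes ~2×10^7 with 10% CV;
* 500 peaks per temporal group plus 2,000 static peaks, NB dispersion
  0.1, closed-state means 10–50 reads, 8-fold open/closed ratio; stage
  means follow the same raw archetype shapes the classifier names, so
  classification accuracy is measurable against truth;
* enhancer-gene links at 3–20 kb TSS distance for 30% of dynamic peaks,
  with a DE table whose class over-representation is *calibrated*: the
  enriched classes' expected observed/expected ratio equals the
  configured target exactly (the background DE rate is solved from the
  class share), so enrichment-score recovery can be asserted within a
  tolerance. Because desk-scale peak spacing lets unlinked peaks capture
  their neighbours' genes through nearest-TSS assignment,
  `simulate_de_table()` can calibrate against the analysis' own link
  table: the planted targets become the genes whose class-labeled links
  all come from the enriched classes, and the background rate is solved
  over exactly the universe the enrichment later measures (this reduces
  algebraically to the truth-universe formula when each gene is linked
  only by its own peak);
* tissue H3K27ac replicate sets with planted class overlaps (same
  calibration: the pancreas set over-represents `PE^ON` 4-fold by
  default), edge-jittered replicates, and private background regions;
* two scRNA-seq datasets of five NB clusters sharing three signature
  gene sets — the planted truth for alignment precision/recall.

Realism limits worth noting: peaks are placed without overlap on a
two-chromosome 20 Mb toy genome; counts are independent across peaks (no
spatial correlation, no GC or mappability structure); the DE table is
drawn directly rather than from an expression model; scRNA clusters are
spherical in log space with a single doublet-free library-size regime.
These generators exist to give the statistics a measurable target, not to
imitate every artefact of real data.

## Reproducibility and numerics

* All stochastic steps take explicit seeds; generator streams are derived
  from one master seed per component label, so adding a generator never
  perturbs another, and the global RNG state is saved and restored.
* The pipeline (`run_pipeline()`) is deterministic: re-running with the
  same config and inputs produces byte-identical tables, and the JSON
  manifest records the seed, all thresholds, and input checksums.
* Problem sizes: the default synthetic workspace (5,000 peaks, 10
  samples, ~1,000 cells per scRNA dataset, 1,000 bootstrap replicates)
  runs end-to-end in a few minutes on one CPU; interval operations are
  exact at atlas sizes in the tens of thousands.

## Limitations

* The NB test assumes counts are insertion counts in fixed peaks;
  peak-calling uncertainty is out of scope (the atlas is an input).
* The 8-to-6 archetype merge presumes the five-stage design; other stage
  counts require a custom archetype library.
* Nearest-TSS linking is a heuristic; it ignores topological domains,
  chromatin loops and strand, and assigns at most one gene per peak.
* The chi-squared enrichment test is asymptotic; for small expected
  counts use the permutation option.
* Cluster alignment compares mean profiles only; it will not detect
  partial or nested cluster correspondences beyond `rank_depth`.
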
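---
title: "Comparing microbial community fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing microbial community fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commfinger)
```

`commfinger` asks a practical question about microbiome monitoring in
anaerobic digestion: when the same digester samples are profiled both by
16S rRNA amplicon sequencing (OTU tables, hundreds of taxa) and by TRFLP
fingerprinting (a few dozen terminal restriction fragment lengths), which
ecological conclusions agree? This vignette documents the statistical
model behind each stage, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where more than one defensible option existed.

## Data model

Everything flows through one container: a feature × sample matrix of
non-negative abundances (`abundance_table`), with features either OTU ids
or TRF fragment lengths in nucleotides. TRF identity is a *string* identity
after canonical one-decimal formatting ("87.4"), because upstream peak
binning happens in the sizing software and this package deliberately
consumes binned tables — it performs no electropherogram processing.
Metadata travels as a tibble keyed by `sample_id`, with missing cells kept
as `NA` and excluded listwise per analysis; no imputation is performed
because none can be justified from operational monitoring data alone.

## Preprocessing

Re-sequenced libraries of one sample are **collated by element-wise count
summation**, which preserves total sequencing depth. A per-feature
relative-abundance range across member libraries is attached as a
diagnostic rather than enforced as a gate: a repeated-measures consistency
check belongs to the analyst, not to an automated filter.

**Common-scale rescaling** converts each sample to proportions, multiplies
by the minimum library size and rounds. "Nearest integer" is ambiguous at
.5 ties, so the rule is fixed and documented: round half away from zero.
After rescaling every column sum sits within (number of features)/2 of the
common depth.

The **1% relative-abundance cutoff** retains features reaching ≥1% in at
least one sample (both thresholds configurable). The cutoff is evaluated
*before* rescaling by default: relative abundance is invariant to the
rescaling except at rounding boundaries, so evaluating it on the raw
proportions avoids rounding artifacts; the literal rescale-then-cutoff
order is available via `preprocess_config(cutoff_stage = "after_rescale")`.
A regression test confirms the two orders disagree only for features whose
proportion sits within one count of the threshold at the common depth.

**Free ammonia** is derived from total ammonia nitrogen, pH and
temperature through the ammonium/ammonia equilibrium with the dissociation
constant's van 't Hoff form, constants 0.09018 and 2729.92 (the
Anthonisen parameterisation widely used in digestion work). The FAN/TAN
fraction rises strictly with pH and temperature — both directions are
property-tested.

## Alpha structure

Hill numbers give diversity in common units of effective taxa:
`H0` richness, `H1 = exp(−Σ p log p)`, `H2 = 1/Σ p²`, computed over
positive-abundance features; `H0 ≥ H1 ≥ H2 ≥ 1` always.

Evenness uses the Lorenz curve of cumulative relative abundance against
cumulative fraction of taxa ranked by decreasing abundance. Two statistics
are deliberately kept distinct, since the literature sometimes conflates
them:

* **Co (community organisation)** = 100 × Gini coefficient: twice the
  trapezoid-rule area between the Lorenz curve and the diagonal, in the
  population form (no n/(n−1) correction). A perfectly even community has
  Co = 0.
* **Pareto** = the Lorenz ordinate at taxon fraction 0.20, linearly
  interpolated when 0.2·H0 is not an integer: the percentage of total
  abundance carried by the top 20% of taxa (range 20–100).

Both are scale invariant and Co is non-decreasing under
concentration-increasing (Pigou–Dalton) transfers; both properties are
tested on random compositions.

Cross-method agreement per statistic uses Spearman's ρ with average ranks
and a two-sided P from the t approximation — adequate for the n ≈ 30
regime this package targets — plus a one-way ANOVA P for a mean shift
between methods.

## Beta diversity

Five dissimilarities are provided. Bray-Curtis, quantitative Jaccard
(`2B/(1+B)`), Kulczynski and abundance-based Chao are delegated to
`vegan::vegdist`; the quantitative Jaccard is the default variant because
the comparison operates in an abundance-based framework throughout (the
binary form sits behind a flag). Since `2B/(1+B) ≥ B` on [0, 1], the
quantitative Jaccard dominates Bray-Curtis element-wise — used as a
cross-metric sanity test.

**Mountford's index** is implemented natively because its scaling
deserves an explicit convention. For presence sets of sizes `a`, `b`
sharing `j` species, θ is the positive root of
`exp(aθ) + exp(bθ) = 1 + exp((a+b−j)θ)`, found by bracketed bisection to
1e-10 with the upper bracket grown by doubling. θ grows without bound as
the sets approach nesting, so the dissimilarity is reported as
`1 − min(θ, log 2)/log 2`: identical sets give 0, disjoint sets
(θ = 0) give 1. Degenerate cases (`j = 0`, `j = min(a,b)`) are handled by
their analytic limits rather than by the solver. The solver is verified
against a two-stage fine-grid scan to 1e-6 and against vegan's
independently coded Mountford distance (which equals `log 2 − θ`).

**NMDS** minimises Kruskal stress-1 by monotone regression from multiple
random starts (50 by default) via `vegan::metaMDS` with transformations
disabled, k = 2, and the final configuration centred and rotated to
principal axes. The run is deterministic for a fixed seed, and the
best-of-restarts stress is non-increasing in the number of restarts.

**Matrix concordance** correlates the paired lower triangles of two
distance matrices (Spearman t-approximation; Kendall with tie-corrected
normal approximation). These P-values ignore the exchangeability structure
of distances; a Mantel permutation option (`mantel_permutations = 9999`)
is provided for users who want permutation-correct inference, but the
plain rank correlations remain the default because they are the statistic
being compared across methods. By default concordance is computed on the
aligned intersection of samples present in both tables.

## PERMANOVA, CCA and envfit

PERMANOVA partitions the Gower-centred squared-distance matrix
(McArdle–Anderson) into between/within-group sums of squares; the
pseudo-F's null distribution comes from free, unrestricted permutation of
labels (no strata). P-values use the `(1 + exceedances)/(1 + permutations)`
convention, so the floor is `1/(n+1)` and P is never zero. 9,999
permutations is the default. Implementation is `vegan::adonis2`, verified
two ways: the pseudo-F equals a brute-force decomposition from explicit
group sums on small Euclidean embeddings, and for n ≤ 7 the permutation P
equals exhaustive enumeration when the full permutation set is supplied.
Pairwise cluster tests Bonferroni-adjust across cluster pairs only — not
across distance metrics — matching how such tables are conventionally
reported. Type-I error is simulation-tested at α = 0.05 (1,000 null
datasets, n = 20, 999 permutations).

CCA is chi-square-standardised correspondence analysis projected onto the
constraints (`vegan::cca`); constraints are z-scored by default and the
flag is recorded, so arrow scales are comparable across variables whose
units differ by orders of magnitude (pH vs mg N/L). Collinear constraints
are rejected up front with the name of the dependent column, rather than
silently aliased. `env_fit` fits each variable marginally onto the
ordination axes (R² = squared multiple correlation; P by permuting the
variable's values, seeded), matching per-variable significance tables;
constant variables return R² = 0, P = 1 with a warning instead of an
error, since operational datasets often carry degenerate columns.

## Co-occurrence networks

All feature pairs are screened by Spearman correlation across samples
(average ranks; two-sided t-approximation P). An edge requires
`|ρ| > 0.5` **and** `P < 0.001` by default — both signs qualify, and the
screen's P-values are deliberately *not* multiplicity-adjusted, mirroring
the fixed-cut convention of fingerprint network studies; a
Benjamini–Hochberg mode exists and is labelled as a deviation. The null
false-edge rate of the screen is simulation-tested against the same test
applied marginally to independent pairs.

Topology ignores edge sign and weight. Betweenness is Brandes'
shortest-path count (igraph), reported raw by default with a
`2/((n−1)(n−2))`-style normalisation flag; comparisons between networks of
different size should use the normalised option (the report records which
was used). Normalised degree is `degree/(n−1)`. Isolated nodes are kept
with zeros — the *fraction* of isolated features is itself a headline
statistic of fingerprint networks. Betweenness is verified against a
brute-force all-shortest-paths enumeration on all random graphs up to 10
nodes. Node-level differences between two networks use Mann–Whitney
tests, chosen over t-tests because betweenness distributions are strongly
right-skewed with many zeros.

## The synthetic generator

`generate_paired_dataset()` emulates the statistical structure the
analysis assumes, at the scale of a 25-plant, 33-sample digester survey:

* **Clusters and gradients.** Plants are allocated to 4 clusters
  (weights 4:3:10:8) with pH centroids 7.15/7.50/7.85/8.20 and temperature
  centroids 33/36/38/52 °C — three mesophilic process types and one
  thermophilic cluster, spanning the operational ranges reported for
  full-scale digesters (pH ≈ 7.1–8.5, TAN up to several g N/L). Per-OTU
  log-abundance responds linearly to the standardised pH and temperature
  gradients (loading SD 2.0 each), so community composition is *caused*
  by pH and temperature and envfit has a recoverable truth.
* **Abundances.** 1,200 OTUs with log-normal base abundances (shape 1.2)
  plus per-sample log-normal noise (SD 0.8), multinomially sampled at a
  log-normal depth centred on 40,000 reads (SD 0.4 on the log scale), so
  the common-scale rescaling stage is non-trivially exercised.
* **TRF tables.** Each OTU maps to one fragment length drawn uniformly
  from a 6-nt grid of 74 lengths, giving the heavy many-to-one collision
  load that makes fingerprinting lossy; each OTU × sample measurement is
  jittered by Gaussian sizing noise (SD 0.39 nt), binned to 1 nt,
  aggregated, thresholded by a 0.5% within-sample detection floor and
  renormalised to the pre-threshold column total (so totals are
  conserved). The floor sits deliberately *below* the 1% analysis cutoff:
  fingerprinting detects sub-1% peaks that the cutoff later removes,
  which is why the cutoff visibly reduces the TRF feature count.
* **Archaea.** An independent pool of 12 TRFs with temperature
  affinities; per-sample richness is Poisson with mean 4 (truncated to
  ≥1), reproducing the low-richness archaeal fingerprint.
* **Determinism.** One master seed, split into per-stage streams
  (metadata, OTU, fragment map, archaea), so changing archaeal parameters
  never perturbs the bacterial draws.

`degrade_resolution()` isolates the information-loss mechanism: it re-maps
a chosen fraction of OTUs onto already-occupied fragment lengths and
re-aggregates with no noise or floor, conserving column sums exactly.
Cross-method Bray-Curtis concordance declines monotonically in the
collision rate — but only from a fine-resolution baseline; the
monotonicity experiments therefore use a 1-nt grid where the initial map
is nearly one-to-one. Starting from an already heavily collided map,
random re-mapping is not monotone in expectation.

What the generator does **not** emulate: sequencing error and chimeras,
compositional correlation structure beyond the shared gradients, true
restriction digestion of real 16S sequences (fragment lengths are
arbitrary), temporal autocorrelation of repeat samples, and taxonomic
identity. Passing tests therefore demonstrate that the *pipeline*
recovers planted structure under realistic dimensions and noise — not
that any particular real digester will show the same effect sizes.

## Problem sizes and runtime choices

The test-suite simulations are sized to run comfortably on one CPU:
type-I-error and envfit null calibrations use 1,000 simulations with 999
permutations each at n = 20; metric axioms run on 500 random tables;
betweenness equivalence on 200 random graphs (≤10 nodes); exhaustive
PERMANOVA enumeration at n = 6 and 7; end-to-end recovery on the full
33-sample preset with 9,999 permutations; and the collision-rate
experiment uses 20 replicates of a 10-sample configuration. Pipeline
smoke tests use a reduced 8-plant/10-sample configuration since they test
plumbing, not power.

## Known limitations

* Repeat samples from one plant are treated as independent in all
  statistics; the plant id is carried in the metadata so users can apply
  their own restricted designs, but no mixed-model or restricted
  permutation scheme is built in.
* The Spearman screen inherits the compositionality of relative-abundance
  data; no SparCC/SPIEC-EASI-style correction is attempted.
* Mountford and the binary Jaccard discard abundance information by
  construction; Chao requires count data to locate shared singletons and
  doubletons, so it is not meaningful on renormalised TRF intensities.
* NMDS stress comparisons across tables of very different feature counts
  should be read qualitatively; stress depends on n and on tie structure.
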
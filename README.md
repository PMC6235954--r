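# commfinger

Cross-method comparison of microbial community fingerprints in R.

## The problem

Full-scale anaerobic digesters are monitored through their microbiome, but
the two common profiling routes disagree in resolution: 16S rRNA gene
amplicon sequencing yields hundreds of OTUs per sample, while terminal
restriction fragment length polymorphism (TRFLP) collapses the community
onto a few dozen fragment lengths. Operators and researchers need to know
*which conclusions survive the cheaper fingerprint*: is a TRFLP profile a
reliable proxy for amplicon data when tracking diversity, community shifts
and their operational drivers (pH, temperature, ammonia)?

`commfinger` implements that comparison as a reusable, tested pipeline for
paired feature-by-sample abundance tables (OTU counts and TRF
relative-abundance tables keyed by fragment length), plus a synthetic
paired-profile generator with known ground truth so the whole analysis can
be exercised and validated without external data.

## What it computes

* **Preprocessing** — collation of re-sequenced libraries (element-wise
  count sums), common-scale rescaling (each sample's proportions times the
  minimum library size, rounded half-away-from-zero), the ≥1%
  relative-abundance cutoff, and free ammonia from total ammonia nitrogen:
  `FAN = TAN · (1 + 10^(−pH) / 10^(−(0.09018 + 2729.92/T_K)))^(−1)`.
* **α-diversity** — Hill numbers `H0` (richness), `H1 = exp(Shannon)`,
  `H2` (inverse Simpson); Lorenz-curve community organisation
  `Co = 100 × Gini` and the Pareto value (cumulative relative abundance of
  the 20% most abundant taxa); Spearman + ANOVA comparison of each
  statistic between methods.
* **β-diversity** — Bray-Curtis, quantitative Jaccard, Kulczynski,
  abundance-based Chao and Mountford dissimilarities; NMDS (Kruskal
  stress-1, multi-start); Spearman/Kendall concordance between the two
  methods' distance matrices (optional Mantel permutation test).
* **Constrained inference** — PERMANOVA (McArdle–Anderson pseudo-F,
  seeded free permutations, pairwise cluster tests with Bonferroni
  correction) and CCA with permutation-based environmental vector fitting.
* **Co-occurrence networks** — all-pairs Spearman screen
  (|ρ| > 0.5, P < 0.001 by default), Brandes betweenness centrality and
  normalised degree, and a Mann-Whitney comparison of node statistics
  between networks.
* **Synthetic data** — 33 samples from 25 plants in 4 pH/temperature-driven
  clusters, log-normal OTU abundances multinomially sampled at ~40,000
  reads, a many-to-one OTU→fragment-length map with 0.39 nt sizing noise
  and a detection floor, and a low-richness (~4 TRFs/sample) archaeal
  profile — all deterministic per seed, with the truth record returned.

## Worked example

```r
library(commfinger)

ds  <- generate_paired_dataset(synthetic_config(seed = 42))
otu <- preprocess_table(ds$otu)              # collate + 1% cutoff + rescale
head(alpha_diversity(otu), 4)
#> # A tibble: 4 × 6
#>   sample_id    H0    H1    H2    Co Pareto
#>   <chr>     <int> <dbl> <dbl> <dbl>  <dbl>
#> 1 P01          77  10.8  4.91  85.8   89.2
#> 2 P02          71  21.1 13.4   77.1   81.6
#> 3 P03          66  13.7  6.07  81.3   85.2
#> 4 P04          65  11.1  5.06  84.6   89.5

dm <- distance_matrix(otu, "bray_curtis")
permanova(dm, setNames(ds$metadata$cluster, ds$metadata$sample_id),
          n_permutations = 9999, seed = 42)
#> <permanova_fit> grouping on bray_curtis distances: pseudo-F = 16.022,
#>   R2 = 0.624, P = 0.0001 (9999 permutations)

trf <- preprocess_table(ds$trf_bacterial, rescale = FALSE)
matrix_concordance(dm, distance_matrix(trf, "bray_curtis"))
#> # A tibble: 1 × 5
#>   spearman_rho spearman_p kendall_tau kendall_p n_pairs
#> 1        0.859  9.00e-155       0.681 1.22e-120     528

cooccurrence_network(otu, 0.5, 0.001, normalised_betweenness = TRUE)
#> <cooccurrence_network> 132 nodes, 4564 edges (52.8% of potential), 0 isolated

free_ammonia(TAN = 1000, pH = 8.0, temperature_C = 35)
#> [1] 101.041
```

The per-sample table reads: sample P01 holds 77 taxa at ≥1% resolution,
but they behave like only ~11 equally common taxa (`H1`), with a strongly
uneven community (`Co` 85.8; the top 20% of taxa carry 89.2% of reads).
The PERMANOVA shows the four operational clusters explain 62% of
community variance; the distance matrices of the two methods agree at
ρ = 0.86 over all 528 sample pairs.

The full workflow — both TRF tables, envfit, networks and cross-method
tests — runs through `run_full_comparison()`; `write_report()` emits the
stage TSVs plus a machine-readable `summary.json`, and `autoplot()` /
`plot_lorenz()` / `plot_network_comparison()` cover the standard figures.

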
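---
title: "tilingsweep: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tilingsweep: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the scientific model behind each pipeline stage, the
tunable parameters with their defaults and units, what the synthetic-data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The measurement model

A tiling array interrogates the genome with 25-mer probes designed against
a reference genotype. When a test accession's DNA carries sequence
polymorphism inside a probe's footprint, the duplex is destabilised and
the hybridisation signal drops; a strong drop marks the probe as a single
feature polymorphism (SFP) for that accession. The simulator implements
this as a multiplicative (log-additive) attenuation model on log2 signal:

* each SNP in a probe contributes `atten_peak * w(pos) * g(gc)` log2 units
  of signal loss, where `w` is a triangular weight equal to 1 at the probe
  centre (position 13 of 25) and falling linearly to near 0 at the ends —
  a centre mismatch disrupts the duplex most — and
  `g(gc) = 1 + atten_gc_slope * (gc - 0.5)/0.5` is a mild linear GC
  modulation (high-GC probes lose proportionally more signal);
* SNP counts per polymorphic probe are `1 + Poisson(0.4)` and attenuations
  add on the log2 scale;
* deleted probes fall to a constant background `background_delta` (default
  4 log2 units, i.e. 16-fold) below the reference signal — segment states
  override per-SNP attenuation, and a duplicated probe likewise sits at
  `log2(dup_fold)` above reference because the extra copies contribute
  reference-like signal regardless of point polymorphism;
* every array value receives independent Gaussian noise (`noise_sd`,
  default 0.35 log2 units), and each accession is hybridised on
  `n_replicate_arrays = 2` replicate arrays.

Defaults were set once so that a centre-of-probe SNP attenuates well past
the −1.5 call threshold (peak 3.2 log2 units) while end-of-probe SNPs
mostly escape calling. Under these conditions the −1.5 threshold yields an
FDR well under 10% with an FNR several-fold larger — the stringency
trade-off the calling procedure is designed around: a threshold chosen to
keep false calls rare necessarily misses many genuinely polymorphic
probes whose SNPs sit near probe ends.

## SFP calling

`normalize_arrays()` defaults to quantile normalisation (via limma),
forcing every array onto the average order-statistic distribution; median
scaling is available. Quantile normalisation assumes arrays share a signal
distribution, so the handful of genuinely amplified probes in a
duplication are compressed toward the bulk maximum — duplication
segmentation is therefore more faithful under median scaling, and the
recovery analyses use it. Calls are made per accession on the mean of
replicate log2 signals (the replicate-combination rule is not dictated by
the measurement model; the mean is the natural estimator). The call
boundary is inclusive: `log2FC <= threshold`. Non-unique probes
(multi-match, a configured 10% of the map) never carry calls. Missing
intensities skip the probe for that accession; no imputation.

## Segmentation

Deletions are maximal runs of at least `min_run = 10` consecutive called
unique probes (about 350 bp at 35 bp spacing — the scale of a typical
exon); duplications are runs of 10 probes at `log2FC >= 2`. Two readings
of the duplication threshold circulate (strictly greater than 4-fold, or
greater than 2-fold); the conservative 4-fold reading is the default and
`min_log2fc` exposes the other. Runs never bridge chromosomes or
intervening non-unique probes, because genome-order adjacency across a
masked probe is ambiguous; strict runs are used (no single-probe
interruptions). Segment extent is first probe start to last probe end.
Deleted probes remain counted as SFPs in totals. On noiseless data every
planted segment of at least `min_run` probes is recovered with at most
one probe of boundary error, and shorter planted segments are never
reported.

## Enrichment

The null for feature classes and gene families is length-proportional:
`expected = total_sfps * class_bp / genome_bp`, with class bp computed on
the union of the class's intervals. A site overlapping several features
counts toward each (overlapping annotations are real; double counting is
the honest convention and is stated in the output). Two tests are
provided because both are defensible readings of common practice: a
two-cell χ² goodness-of-fit on pooled counts (default) and an unpaired
Student's t-test across per-accession observed/expected pairs, where the
per-accession expectation is that accession's SFP total times the class's
genome fraction. Raw p-values are reported alongside a
Benjamini–Hochberg-adjusted column.

## Association

The trait model is linear: `v = intercept + M + Env + Q + error`, fitted
by OLS per (site, trait) on per-experiment records. `Q` holds admixture
proportions; because rows sum to one, the last column is dropped to keep
the design full-rank. When only least-squares means per accession are
available, `Env` is dropped. The marker F is the partial F between the
models with and without `M`. Least-squares means are predictions at
marker 0/1 with the environment factor balanced and `Q` at sample means.

Empirical p-values are pooled across the entire scan (all sites × traits):
`p = #(F >= f)/N`. Pooling across traits is what makes the
expected-random arithmetic coherent: at threshold α the expected number
of random associations is `n_sites * n_traits * α`, and the FDR estimate
is that expectation over the observed significant count (as a
percentage, capped at 100). Per-trait pooling is available as an option.
The default scan threshold is `α = 1e-3` and the pathway threshold
adjusted `p <= 0.01`, both configurable.

Pathway over-representation compares F-scores of SFPs in a pathway's
genes against SFPs in all remaining metabolic genes (one-sided
Mann–Whitney U), BH-corrected across the deliberately short list of
tested pathways. A "metabolic SFP" is any SFP inside an annotated
metabolic gene's interval. Minimum gene-to-metabolite paths run over the
undirected bipartite reaction–compound graph with currency compounds
(water, CO2, O2, protons, ATP/ADP, NADH/NAD) deleted as traversal nodes;
path length is the number of reactions on the chain, so a gene whose
reaction touches the metabolite is at distance 1. Traversal is
undirected because reaction directionality is not modelled; this can
shorten paths relative to a flux-aware metric and is a stated
limitation.

## PHS sweep scan

The physical→genetic map is a least-squares polynomial (default degree
3) per chromosome fitted to a marker table; because a raw polynomial can
dip, evaluation passes through an isotonic adjustment on a dense grid,
and the map reports its marker RMSE. A degree-0 map is rejected outright.

For a pair of accessions, the sharing length at a site is the cM span of
the maximal run of identical markers containing that site; the run ends
at the last identical marker before the first discordant one (not at a
midpoint), chromosome ends truncate, and a pair discordant at the site
itself shares nothing. Pairs are standardised by their own genome-wide
mean and sample SD of sharing (computed over all sites by default;
`grid_step` thins the grid), which is what absorbs genome-wide
relatedness, i.e. population structure. The allele score is the
difference form — mean standardised sharing over carrier pairs minus the
mean over all pairs — with the single-term carrier form behind
`form = "carrier"`; the difference form is the default because it
centres the statistic at zero for an unremarkable allele.

Scores are standardised within allele-frequency classes,
`(PHS − median_f)/SD_f` (median, not mean, because a true sweep drags
the class mean), using exact carrier-count classes when every class has
at least 20 scores and 0.05-wide frequency bins otherwise. The sample
(n−1) SD is used throughout. Each site is then represented by its
better-scoring allele, which is also the putatively selected allele
(longer sharing among carriers). LD pruning iterates over adjacent
retained sites and removes the lower-scoring one when r² > 0.5 with
r > 0, until stable — the operation is idempotent.

Candidate windows contain strictly more than 45% outliers, where
outliers are the top 0.5% of standardized scores genome-wide at study
scale. Overlapping candidate windows merge; region bounds are the first
and last SFP of the merged windows; the focal SFP is the region's top
scorer. The geographic test compares haversine distances (spherical
Earth, radius 6371 km) among carriers of the selected allele with pooled
distances from label permutations across all accessions, one-sided
(carriers closer); the per-pair pooled comparison is the default, and
the test is deterministic given its seed.

## What the generator emulates, and what it does not

The generator reproduces the statistical structure the analysis relies
on: position/count/GC-dependent probe attenuation; contiguous
deleted/duplicated segments; a 4-population admixed sample built from
Balding–Nichols-differentiated founder haplotypes (FST 0.15) copied in
geometric blocks; a planted sweep implemented by copying one founder
haplotype across a carrier subset so carriers are pairwise identical
over the region (carrier count rounds half up); traits generated from
exactly the association model; geography scattered around population
centres; a connected reaction network with currency co-factors; and a
monotone cubic genetic map whose marker noise scales with the map span.

It does not emulate realistic sequence content, coalescent genealogies,
probe cross-hybridisation beyond the binary uniqueness flag, CEL-level
artefacts, or linkage between the sweep and the geographic origin of its
carriers (carriers are drawn across populations). Passing tests
therefore demonstrate the pipeline's correctness and calibration under
the stated generative assumptions, not performance on any particular
real array dataset.

## Problem sizes and scaled settings

Desk-scale defaults (chosen once as the package's own test conditions):
54 accessions, 5 chromosomes × 1200 probes at 35 bp spacing for
calibration summaries; 16 accessions × 800 probes for noiseless segment
recovery; 24 accessions, 2 × 1250 probes with a 300-probe planted sweep
(carrier fraction 0.6, background mosaic blocks of 20 probes) for sweep
recovery. At study scale the window rule is 1000 SFPs / offset 50 / top
0.5% outliers; those proportions cannot be satisfied on a few hundred
sites (45% of a 1000-SFP window needs at least 450 outliers, but 0.5% of
a desk-scale genome is a handful), so scaled runs use window 100, offset
5 and an outlier quantile of 0.08 — preserving the structure of the
rule: the planted sweep spans roughly the window, and the outlier budget
is a small multiple of the sweep's site count. Sweep recovery is
evaluated on the simulator's genotype matrix; calling noise (the FNR of
stringent thresholds) shatters pairwise haplotype identity and biases
sharing lengths, which is a recognised limitation of sweep detection on
SFP calls rather than of the scan itself.

## Numerical conventions and degenerate inputs

Ties at the call threshold are calls. Empirical p uses `>=` (so the
maximum score of N gets p = 1/N, never 0). Zero-variance frequency
classes standardise to 0 with a warning; zero-variance pairs are
excluded from PHS with a warning; a Mann–Whitney on complete ties
reports p = 1. `estimate_fdr` warns and caps at 100% when the expected
random count exceeds the observed. Empty segment tables, families with
no intervals, and constant window profiles (undefined correlations,
reported as NA) are all handled explicitly. All generators are pure
functions of `(config, seed)`; the pipeline derives per-stage seeds from
the global seed so stages are independently reproducible.
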
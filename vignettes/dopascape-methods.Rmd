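---
title: "Methods: clustering a social-experience epigenetic landscape and scoring its behavioral readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering a social-experience epigenetic landscape and scoring its behavioral readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

Group housing (GH) and single housing (SH) are a classic social-experience
contrast in *Drosophila*: a few days of isolation reduce daytime sleep and
shift gene expression in dopaminergic neurons. `dopascape` implements the
downstream analysis of such an experiment, starting from per-gene
quantifications of six histone marks (H3K4me3, H3K27ac, H3K9/K14ac,
H3K36me3, H3K9me3, H3K27me3) and mRNA in the two conditions, and from
1-minute activity-monitor traces. Everything upstream — alignment, island
calling, normalization between libraries, differential-expression modeling —
is out of scope: the package consumes already-quantified signal tables.

# The delta landscape and its clustering

## Expressed-gene filter

Genes below the top 40% of mean expression are dominated by replicate noise,
so the landscape is built on the top fraction (`expressed_fraction`, default
0.4) of genes ranked by mean TPM. The ranking statistic is the pooled mean
of the two condition means; GH-only and SH-only rankings are available via
`rank_by` because the pooled choice is a convention, not a forced one. Ties break lexicographically by gene id so the
selection is reproducible. `signal_to_noise_report()` quantifies the
rationale — the share of below-cutoff genes whose within-treatment mean/sd
(reciprocal CV) falls below 1 — but is advisory only and never alters the
filtering.

## z-scored differences

For each signal, the per-gene difference of replicate means (GH − SH) is
z-scored across the expressed genes: each of the 7 columns of the delta
matrix has mean 0 and sample standard deviation 1 (denominator n − 1; the
choice is a convention and is pinned down so the 3-gene worked example
`[1, 2, 3] → [−1, 0, 1]` is exact). z-scoring puts marks with very different
dynamic ranges on one scale, at a price worth knowing: the within-cluster
spread of a column shrinks by that column's total (between + within)
spread, so columns that do not separate clusters keep relatively more noise.
A signal whose difference is constant across genes cannot be z-scored and is
reported as an error naming the signal.

## k-means, k selection and the stability metric

Clustering is Lloyd's k-means over the delta matrix with k-means++ seeding,
best of `restarts` (default 5) initializations by within-cluster sum of
squares, deterministic for a given seed. An empty cluster is re-seeded from
the point farthest from its centroid rather than dropped, preserving the
requested k.

Two k-selection criteria are provided because both are in common use and
genuinely disagree on some data:

* **BIC**: a hard-assignment spherical-Gaussian mixture with shared variance;
  `BIC(k) = −2 log L + (k d + 1) log n` with the likelihood including the
  mixture weights. The weight term matters: without it the criterion
  rewards splitting any cluster larger than roughly `d log n` points.
* **Elbow**: the largest second difference of the inertia curve.

Both return the full diagnostic curve, and a `low_confidence` flag marks
featureless data (a flat BIC range or a weak elbow). On landscapes where
some columns carry no cluster separation the z-induced anisotropy can make
the spherical BIC over-split; the elbow criterion is more robust there, and
the curve should always be inspected. The default candidate range is
2–12 clusters.

The stability procedure re-runs k-means N times (default `n_runs = 46`,
the replication count that yields 1035 run pairs) with seeds
`base_seed + run index`, recorded for replay. For each unordered pair of
runs (i < j) and each cluster c of run i, it records the maximum percent
overlap `100 · |c ∩ c′| / |c|` over clusters c′ of run j — the denominator
is the source cluster's size, which makes a record of "94%" read as "94% of
this cluster reappears intact". This yields exactly `N(N−1)/2` pairs and
`k · N(N−1)/2` records (8280 for N = 46, k = 8), summarized by the median
and the fraction above 99%. Using sources from the lower-indexed run only
(rather than pooling both orientations) is what makes the record count
exactly k per pair.

Cluster profiles are reported re-indexed by ascending mean mRNA z, the
heat-map convention in this literature: cluster 1 is the most SH-shifted in
mRNA, cluster k the most GH-shifted.

# Motif analysis

## Scanning with exact p-values

Motifs are position probability matrices read from MEME minimal files, with
one global background. A pseudocount (default 0.01, background-weighted) is
added to the scoring copy of each matrix so log-odds stay finite; the raw
matrix is kept for round-tripping. Scanning slides the motif over both
strands and scores each window by the summed log2 odds against the
background. The hit threshold is derived from the *exact* null distribution
of the score — computed by dynamic programming over motif columns with
scores discretized on a fixed grid (default granularity 1e-3 bits; every
score is then within L·g/2 of exact, and per-cell scores are snapped to the
grid so the scanner and the distribution agree bit-for-bit). The threshold
realizes the largest attainable p ≤ `p_threshold` (default 1e-4, the
conventional per-position scanning default). Windows containing N are
skipped; overlapping hits and both strands all count, so a
reverse-complement-palindromic site counts twice, once per strand — this is
deliberate and documented rather than deduplicated, because strandedness of
binding is not resolvable at this level.

The promoter window is TSS ± 500 bp (1001 bp, odd so the TSS is centered),
built from BED6 annotation with 0-based half-open coordinates internally;
windows clipped at a contig edge are flagged.

## Enrichment, TF filtering, regression

Per-cluster enrichment compares genes carrying ≥ 1 predicted site in the
cluster against an equal-sized control set drawn without replacement
(seeded) from the non-cluster universe, with a one-sided hypergeometric
test, Bonferroni-adjusted over motifs, and an intentionally extreme call
threshold (adjusted p < 1e-10). The reference tool for this step tests
positional concentration of best sites; restricting to the fixed ±500 bp
window already encodes the positional constraint, so presence/absence in
the window is the statistic here. Both gene-level presence counts and total
site counts are emitted, since either could drive a call.

TF filtering keeps motifs whose TF gene is itself expressed and moves by at
least 33.3% between conditions — the symmetric reading
(`max(GH,SH)/min(GH,SH) ≥ 4/3`), since "change in transcript levels" is
directionless. Motifs with no mapped TF go to a flagged unmapped bin.

The regression is ordinary least squares of per-gene log2 fold change
(pseudocount 0.5 on both means before the ratio) on per-gene motif counts,
with backward elimination: the largest-p predictor is dropped and the model
refit until all retained p-values clear the gate. The default gate is
`alpha = 0.05` ("remove until only significant variables remain"). Under
that gate a retained-but-marginal predictor cannot occur; the alternative
`drop_gate = "marginal"` stops at `alpha_marginal = 0.10` and annotates
predictors in [0.05, 0.10) with a parenthesized sign, the "(−)" notation of
TF-group regression tables. A known property of p-gated backward
elimination worth stating plainly: each null predictor survives at roughly
the per-predictor rate alpha, so with m predictors the chance that *some*
null predictor survives is roughly 1 − (1 − alpha)^m, not alpha. The tests
assert the per-predictor rate. Perfectly collinear predictor pairs keep the
earlier-listed member; constant predictors are dropped, both with warnings.
Reported per group: multiple correlation r = √R² of the final model, the
overall F-test p, and a sign per retained predictor.

# Gene-set statistics

The sign test is the exact binomial at p = 1/2; sidedness is an explicit
argument with no default hidden behind a convention, because the two
reference uses of it (14/15 mitochondrial genes, p = 0.0005; 9/9 shared
activity-regulated genes, p = 0.004) are only reproduced by one-sided and
two-sided readings respectively. Two-gene-set comparisons (e.g. targets
repressed vs activated by a TF, per mark, with no cross-mark adjustment)
default to Welch's t; the pooled-variance reading cannot be ruled out from
a printed t and df alone, so `wilcoxon` and Welch are both exposed and
singleton sets are redirected to the rank test. External fold-change lists
enter as plain per-gene vectors and are compared by Pearson correlation on
the gene-id intersection.

# Sleep scoring and the interaction test

A sleep bout is a maximal run of ≥ 5 consecutive zero-count minutes; every
minute inside a bout is asleep. Daytime sleep sums asleep minutes over
[ZT0, ZT12) of the scored 24-h window (12/12 light cycle), so a bout
spanning lights-off contributes only its daytime minutes. Monitor traces
must be dense: any gap rejects the trace, since beam-break monitors emit
dense data and imputing zeros would manufacture sleep. The first
(acclimation) night is trimmed by the reader (`trim_minutes`), and
generated traces point their ZT0 at the final simulated day for the same
reason.

ΔSleep — GH daytime sleep minus SH — is a group-level difference with no
per-fly replicates, so the knockdown question ("does RNAi in dopaminergic
neurons reduce the social effect on sleep?") is operationalized as the
genotype × housing interaction in a Type III ANOVA on per-fly daytime
sleep. Type III sums of squares are computed by full-vs-reduced model
comparisons with sum-to-zero contrasts (each term's SS is the residual-SS
increase when its model-matrix columns are removed from the otherwise full
model); on balanced designs this equals the classical two-way
decomposition, and the implementation is cross-checked against an
independent one on unbalanced data in the test suite. Saturated zero-noise
fits report F = 0 for zero-SS terms instead of 0/0.

# What the synthetic generators emulate — and what they do not

All inputs can be generated with planted truth, making every stage testable
without downloads. The defaults mirror the study scale: 7 signals, 8
clusters, 5372 genes (the top-40% set), 3 replicates, 1001-bp promoters,
12/12 light cycle, 32 flies per group.

* **Landscape** (`gen_landscape`): per-gene cluster label, then per-signal
  GH−SH deltas ~ Normal(cluster mean, within-sd 1), split around log-normal
  baselines (meanlog 5) into replicate tables with noise sd 0.5. Cluster
  mean patterns put an increasing mRNA ramp across clusters and ±1
  Hadamard-design mark patterns, scaled by `separation` (default 5, i.e.
  well-separated at ≥ √3·separation between any two clusters). Values are
  truncated at zero; baselines are large enough that this is rare. Not
  emulated: mean–variance coupling of counts (so the signal-to-noise
  diagnostic is uninformative on synthetic data), correlated marks,
  heavy-tailed expression, batch structure. Recovery results on this
  generator therefore show algorithmic correctness, not robustness to real
  ChIP noise.
* **Promoters** (`gen_promoters`): per-gene planted site counts
  ~ Binomial(6, 0.25) per motif, exact consensus copies planted at
  non-overlapping positions on random strands in i.i.d. background
  sequence, and log fold change = counts·β + Normal(0, 0.5). Planted
  consensus sites are exact so that scanned counts are always ≥ planted
  counts (background can add chance sites); motif length ≥ 8 keeps the
  consensus above the 1e-4 scan threshold. The default five motifs carry
  the field's activity-regulated TF names with dominant negative planted
  coefficients (Hr38 −0.3, cbt −0.25, CrebA −0.2, sr +0.2, pho 0),
  mirroring the repressive sign pattern such tables show. Not emulated:
  dinucleotide background structure, positional site preferences, motif
  families with overlapping specificity.
* **Behavior** (`gen_activity`): per-minute two-state Markov chain with
  day/night transition rates per housing × genotype cell; awake minutes
  emit Poisson(λ = 2) counts, asleep minutes zero. λ = 2 keeps the chance
  of five consecutive awake zero-minutes around 1e-4 per window, so the
  bout scorer identifies the latent state almost perfectly. Day rates
  (GH p_sleep 0.05 / p_wake 0.07; SH 0.022 / 0.105) were set once to give a
  control ΔSleep near 170 min — the order of magnitude seen in
  social-experience sleep assays — and an RNAi genotype removes 60% of the
  GH−SH gap in daytime sleep propensity. The planted expectation uses the
  stationary asleep fraction times the length-biased share of geometric
  bouts reaching 5 minutes, `q⁴(5 p_wake + q)`; this closed form ignores
  light-boundary effects, which is why recovery tests use a 3·SEM band
  rather than exact equality. Not emulated: circadian ramping within the
  day, siesta structure, inter-fly variability in rates.

# Numerical choices and degenerate inputs

* Score discretization: granularity 1e-3 bits; distinct within-column
  scores that would collide on the grid raise an error suggesting finer
  bins rather than silently merging.
* Thresholding uses the largest attainable p ≤ target, so the realized
  false-positive rate is never above the requested one; the achieved p is
  returned for exact Monte-Carlo accounting.
* `pct_change` is computed from `max(ratio, 1/ratio) − 1` so it is exactly
  symmetric in the two conditions; direction lives only in the sign of
  log2fc.
* Fold-change pseudocount default 0.5 expression units, configurable;
  avoids division by zero at unexpressed genes.
* k-means k is bounded by n/10 on delta matrices to keep per-cluster
  estimates meaningful; seeds are always explicit and restored afterwards
  so library calls never perturb the caller's RNG stream.
* Ties at equal PWM score report all positions; assignment TSVs and
  stability JSON are byte-reproducible for a fixed config.

# Problem sizes used by the tests and scripts

The test suite and the acceptance script run the generators at reduced but
structurally faithful sizes chosen for quick iteration: landscapes of
300–1000 genes (the stability and k-recovery runs use 1000 genes, 8
clusters, 46 runs), promoter panels of 60–300 genes, and 8–32 flies per
cell; the analysis scripts use 2500 genes and the full 32 flies per cell.
These sizes keep every planted-truth property measurable (the combinatorial
identities are size-independent, and the statistical checks state their
sampling bands explicitly).

# Known limitations

* The enrichment statistic (window presence/absence, hypergeometric) is a
  deliberate simplification of positional-concentration testing; with the
  extreme 1e-10 threshold both agree on strong signals, but weak positional
  signals inside the window are invisible here.
* The spherical-Gaussian BIC inherits k-means' isotropy assumption; on
  z-scored landscapes with uninformative columns it can over-split, which
  is why the elbow criterion and the full curve are always available.
* The stepwise regression inherits all the usual caveats of post-selection
  inference: reported per-coefficient p-values are conditional on the
  selection path.
* The closed-form planted ΔSleep ignores light-boundary bout effects
  (small relative to between-fly SEM at the default group sizes).
* Signals are treated as already normalized between conditions; the
  optional median-scaling fallback is a coarse instrument for unnormalized
  inputs, not a substitute for proper library-size normalization.
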
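---
title: "Building a heterogeneous Alzheimer's disease network: models and methods"
author: "hena package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a heterogeneous Alzheimer's disease network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hena)
```

# Overview

`hena` constructs a heterogeneous gene-level interaction network for
Alzheimer's disease research. Nodes are Ensembl gene identifiers (ENSG);
edges carry one of four relation types — protein–protein interaction
(PPI), co-expression, epistasis, and intergenic-region interaction (IGRI)
— together with a type-specific score and a data-source identifier. A
companion node-attribute table holds, per gene, its name and biotype, the
best disease-associated SNP with its GWAS p-value, a positive-selection
p-value, and an aggregated expression Z-score in each of 231 brain
regions: 6 scalar fields plus 231 region fields, a 237-field vector.

Because the cohort-scale inputs of the original resource (consortium
genotypes, brain atlases, interaction databases) are restricted or large,
the package ships a first-class synthetic-data module. Every generator
plants known signals and reports them as ground truth, so each analysis
stage can be verified end to end: planted co-expressed modules must
survive rank aggregation, planted epistatic SNP pairs must top the scan,
planted regional upregulation must surface in the Z-score table.

# Cross-study co-expression by Robust Rank Aggregation

Within each expression cohort, the Spearman correlation $\rho$ is computed
for every unordered probe pair, and pairs are ranked with rank 1 for the
strongest correlation. "Strongest" is interpreted as largest $|\rho|$ so
that strong negative co-regulation is retained; signed ranking is
available via `rankPairs(..., rankBy = "signed")`. Normalized ranks
$r = \text{rank}/N_\text{pairs} \in (0, 1]$ are aggregated across the $k$
cohorts with the Robust Rank Aggregation statistic: for sorted normalized
ranks $r_{(1)} \le \dots \le r_{(k)}$,

$$\rho_\text{RRA} = \min_j \; P\big(\mathrm{Beta}(j,\, k - j + 1) \le r_{(j)}\big),
\qquad \text{score} = \min(k\,\rho_\text{RRA},\, 1),$$

the probability under independent uniform rankings that the $j$-th
smallest rank is as extreme as observed, with a Bonferroni-style factor
$k$ for the minimum over positions. A pair absent from a cohort
contributes normalized rank 1 (least significant) — the most conservative
treatment of missingness. Scores are Benjamini–Hochberg adjusted and
thresholded (default `alpha = 1e-5`); probes are then mapped to genes,
self-pairs after mapping are dropped, and duplicate gene pairs (from
one-to-many probe maps, or A–B vs B–A orientation) collapse to the
maximum — most conservative — score.

At $k = 1$ the score equals the normalized rank itself (the uniform CDF),
and the statistic is monotone non-decreasing in every rank; both
properties are asserted in the test suite, along with agreement with a
Monte-Carlo order-statistic null for $k \le 4$.

# Co-expression in disease-related brain regions

For each of the seven hippocampal-circuit regions affected in Alzheimer's
disease (CA1–CA4, DG, subiculum, SptN), Spearman correlations with
two-sided p-values (t-approximation) are computed on the region's samples
only. Pairs pass if the BH-adjusted p-value is at or below 0.01, then a
quartile filter retains positive correlations at or above the first
quartile of the surviving positive distribution and negative correlations
at or below the third quartile of the negative distribution. Quartiles use
linear interpolation between order statistics (R's default type-7
convention); this choice matters because the cut-offs move with the
convention, so it is fixed and documented. Note the quartile filter by
construction trims the weakest quarter of surviving positives — even
perfectly planted modules lose their weakest surviving pairs, which is the
intended behaviour of the published filter, not an artefact.

# Epistasis scanning

## Phenotypes

Three phenotype families are modelled. Longitudinal cognitive traits (the
packaged 23-trait registry, yielding 46 derived phenotypes) are reduced to
a latest value and an OLS slope per individual. Braak-stage scores
(ordinal 1–6, increasing with age even in healthy individuals) are
age-adjusted by subtracting a loess fit of score on age (span 0.75,
degree 2); residuals of an exactly age-linear score vanish, while for
age-independent scores the residuals track the centered scores up to the
loess fit's edge variability. Ventricular-volume series are reduced to
per-individual OLS slopes (at least two time points required) and then
adjusted by regressing the slopes on age, sex and baseline disease status,
keeping the residuals.

## Test and scan

Marker QC removes SNPs with missing fraction > 0.1, minor allele
frequency < 0.05, or Hardy–Weinberg departure at $p \le 10^{-3}$ by a 1-df
chi-square on genotype counts. The published criterion "call rate < 0.1"
is read as "missing fraction > 0.1" — the literal reading would discard
nearly all markers; the threshold is configurable.

For a SNP pair the model is
$y = \beta_0 + \beta_A g_A + \beta_B g_B + \beta_{AB}\, g_A g_B + \epsilon$
on allele dosages $g \in \{0, 1, 2\}$, and epistasis is the F test of
$\beta_{AB} = 0$ with $(1, n-4)$ degrees of freedom ($F = t^2$ of the
interaction coefficient, identical to the full-vs-reduced sum-of-squares
test — asserted to $10^{-10}$ relative accuracy against that oracle).
Missing dosages are handled by pairwise complete cases. The exhaustive
scan prefilters pairs whose MAF product is at most 0.01 and retains
results below the family threshold ($10^{-8}$ for volume/Braak,
$10^{-5}$ for cognitive traits).

## Bins and region-wise Bonferroni

SNPs inside a gene extended by a 5 kb margin on each side (boundary
inclusive) are assigned to that gene — to every such gene when genes
overlap. SNPs outside all extended genes are assigned to exactly one
intergenic region (IGR) named by the dash-joined ENSG ids of the two
flanking genes; chromosome-terminal SNPs get a single flanking gene plus
the sentinel `*`. For a bin pair with $m$ and $n$ member SNPs the
significance level is $\alpha / (mn)$, the number of SNP pairs the bins
can form; a bin pair is reported when any member pair beats that
threshold, scored by its minimum member p-value (the reduction is not
stated in the published description; the minimum matches the reported
per-interaction p-values). Genic–genic pairs are typed `epistasis`; pairs
touching an IGR are typed `IGRI`.

# Brain-region expression Z-scores

Per donor data set, each probe's mean expression is computed per region;
Z-scores then standardize across probes within each region (the phrase
"in each individual region" fixes the axis; the alternative — across
regions within a probe — is available via `axis = "within_probe"` and
recorded in the output attributes). Per-probe Z-scores are averaged,
unweighted, across the data sets where the probe/region is present, and
probes collapse to genes by keeping the entire regional profile of the
probe with the largest maximum $|Z|$ — one whole profile per gene, never
per-region cherry-picking.

# Integration

All stage outputs are mapped to the ENSG name space (one output row per
row/ENSG combination for one-to-many maps, drops counted). MI-scored PPIs
are filtered at the medium-confidence cut 0.45 (inclusive); PBS-scored
yeast two-hybrid interactions are not filtered. The packaged registry
enumerates the 64 constituent data sets across six data types; scores are
deliberately **not** normalized across sources — an RRA score, a Spearman
coefficient, a PBS and an MI score have different semantics, recorded per
`data_source`. Pseudogene nodes and every edge touching them are removed
(idempotently). IGR composite ids remain in the full edge list but are
excluded from the node-attribute table, which holds genes only. The
"reduced" network variant restricts region co-expression edges to
$|\rho| \ge 0.8$.

# Disease-gene prioritization use case

The case-study graph excludes IGRI edges and region co-expression edges
with $|\rho| < 0.5$ (the sign-ambiguous published wording is read as a
magnitude cut, keeping strong negative correlations). Labels: positives
are GWAS-associated genes united with disease-PPI genes; negatives come
from an external essential-non-disease list, with conflicts resolved
positive-over-negative (logged); the rest are unknown. Features comprise a
biological block (231 region Z-scores plus a disease-region contrast — the
tie-corrected normal-approximation Wilcoxon rank-sum statistic comparing
the seven disease regions against the rest) and a graph block (fraction of
positive labels among nodes at shortest-path distance exactly 1 and 2 in
each typed subgraph; empty neighborhoods score 0). The packaged reference
scorer is a random forest; any fit/score function over the feature table
can replace it. Deep graph embeddings are out of scope, so published
classifier metric values are not reproduction targets — the package
asserts the qualitative ordering instead: on synthetic graphs where
positives cluster, graph-block features beat biological-block features in
holdout AUC in at least 8 of 10 seeded runs. To avoid label leakage, the
neighborhood fractions used as features are computed from training-set
positives only.

# Synthetic data: what it emulates, and what it does not

Generators are deterministic given `(config, seed)` and restore the
caller's RNG state. Design choices, made once:

* **Coordinates** are 1-based inclusive on a single synthetic chromosome;
  a configurable fraction of adjacent gene pairs overlap, and pseudogene
  biotypes are planted so that downstream filtering is exercised.
* **Co-expression modules** use a shared latent factor,
  $y_g = \lambda f + \sqrt{1 - \lambda^2}\,\epsilon_g$, with
  $\lambda^2 = 2\sin(\pi \rho_S / 6)$ converting the target Spearman
  correlation to its Gaussian Pearson equivalent. The target is attained
  at `noiseSd = 0`; measurement noise attenuates it.
* **Genotypes** are Hardy–Weinberg draws ($g \sim \mathrm{Bin}(2, p)$)
  with per-SNP MAF in [0.05, 0.5]; missingness is uniform at random. SNP
  positions are placed both inside gene bodies and in intergenic space
  beyond the 5 kb margins so both bin kinds occur.
* **Planted epistasis** follows the scanned model itself
  ($y = \beta_0 + \beta_A g_A + \beta_B g_B + \beta_{AB} g_A g_B +
  \epsilon$), which makes recovery a calibration check of the scan, not a
  tautology — the scan must find the pair among all $\binom{n}{2}$
  candidates after QC.
* **Braak-like scores** are `round(clip(1 + 4(age-60)/35 + noise, 1, 6))`
  — a smooth age trend with ordinal rounding; the source material states
  only that the score increases with age.
* **Default sizes** are desk-scale (150 genes, 400–500 individuals, up to
  ~50 SNPs, 40 samples per cohort in the default pipeline; the acceptance
  analyses use 1000 null replicates and 10-seed recovery runs), chosen so
  the full pipeline completes in about a minute.

What passing tests do **not** show: the generators draw from clean
Gaussian and binomial families with exchangeable samples. Real microarray
cohorts carry batch effects, outlier samples, heavy-tailed intensities and
correlated noise; real genotypes carry linkage disequilibrium and
population structure (explicitly not corrected for here, matching the
modelled analysis); real region annotations are imbalanced. Recovery of
planted signals therefore validates the statistics and their wiring, not
robustness to those artefacts.

# Numerical choices and degenerate inputs

Constant probes (zero rank variance) are excluded from correlation with a
message rather than propagating undefined values. Collinear epistasis
designs (e.g. $g_A g_B$ constant) return an undefined-test marker and the
pair is skipped. Regions with zero expression dispersion are dropped from
Z-scoring per data set. All-identical ages fall back to mean-centering
with a warning. Empty surviving-pair sets are empty tables, not errors.
Ranking ties use average ranks; candidate-ranking ties break
lexicographically by ENSG id. Pair tables are canonicalized so `id_a <
id_b` lexicographically; no table ever contains both orientations.

# Known limitations

* The probe-variance prefilter (SD > 0.29) of the original preprocessing
  is tied to real array intensity scales; the synthetic module exposes the
  threshold but cannot reproduce the scale, so it is not applied by
  default.
* Whether stricter per-cohort QC presets (missing > 0.15, HWE
  $p < 10^{-6}$) or the general ones apply is cohort-dependent; both are
  reachable through `qcFilter` arguments.
* The default pipeline scans the planted quantitative phenotype and
  derives — but does not exhaustively scan — all 46 cognitive-trait
  phenotypes; a full scan is a loop over `scanPairs` with the
  cognitive-trait threshold and is omitted from the default run for
  runtime proportionality.
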
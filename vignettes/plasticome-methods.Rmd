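---
title: "Methods: dissecting transcriptome plasticity across vineyards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting transcriptome plasticity across vineyards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasticome)
```

## The problem

Phenotypic plasticity is the range of phenotypes one genotype expresses
across environments. In a vegetatively propagated crop such as grapevine,
a single clone grown in many vineyards gives a clean window on it: any
expression difference between sites is environmental (or agronomic), not
genetic. plasticome implements the analysis pipeline for such a design —
berries of one clone sampled in many vineyards at three ripening stages
(veraison, mid-ripening, fully ripe) with three biological replicates,
profiled on a one-channel microarray — and classifies genes as:

* **plastic** — modulated across vineyards within one season;
* **developmental markers** — monotonically up- or down-regulated across
  stages identically in every vineyard;
* **constitutive** — neither stage- nor vineyard-modulated, with minimal
  variance: candidate reference genes for expression normalization;
* **factor-associated** — tracking an agronomic or environmental factor
  shared by groups of vineyards (trellis system, macro-area, rootstock).

Sample names encode the design (`<VINEYARD><YY><STAGE>[<REP>]`, e.g.
`AM082B`), and every analysis derives its grouping from the names, so a
plain TSV matrix is a complete input.

## Pipeline stages and their statistics

### Unimodal gene selection

Whole-array log2 intensity histograms are typically bimodal: a low mode of
probes at background level under the expressed genes. Testing low-signal
genes wastes power and corrupts rank statistics, so the pipeline first
removes the low bimodal component: k-means over per-gene intensity
profiles (Euclidean) is run for k = 2, 3, ... until exactly one cluster
pools to a bimodal value distribution *and* that cluster has the lowest
mean intensity; all other genes form the unimodal set.

Bimodality is judged by Sarle's coefficient
$b = (g_1^2 + 1)\,/\,(g_2 + 3(n-1)^2/((n-2)(n-3)))$ with bias-corrected
sample skewness $g_1$ and excess kurtosis $g_2$. The threshold 0.555 sits
just below the uniform-distribution benchmark 5/9: flatter-than-uniform
(i.e. two-humped) distributions exceed it, a Gaussian scores about 1/3.
The choice of statistic is ours — published analyses of this kind often
judge the histograms visually, which is why reported unimodal-set sizes
cannot be reproduced exactly — and a two-component Gaussian-mixture BIC
comparison is available as an alternative (`criterion = "gmm_bic"`).
Sarle's $b$ is known to be sensitive to heavy tails: a percent of stray
high-intensity genes attached to the low cluster can mask its bimodality,
which is why the sweep examines clusters (tight intensity strata) rather
than the pooled array.

k-means uses seeded farthest-point initialization with 10 restarts (best
within-cluster sum of squares kept), making the whole sweep deterministic
for a given seed. Ties in "minimal mean" break toward the larger cluster.

### Plastic genes

On the unimodal set of a one-year, 11-vineyard table, a gene is plastic
when the tie-corrected Kruskal-Wallis test across the 11 vineyard groups
(stages and replicates pooled; 9 samples per group) gives p < 0.01. The
non-parametric test is the standard choice here because per-gene intensity
distributions are not reliably Gaussian at this scale.

The companion summary reports the average number of ripening-modulated
genes per vineyard: a Kruskal-Wallis test across the three stages *within*
each vineyard, at the same alpha. With three replicates per stage this test
has only nine observations, where the chi-square approximation cannot reach
p < 0.01 at all (the largest attainable H of a 3/3/3 design is 7.2,
p ≈ 0.027). The per-vineyard screens therefore use the exact permutation
null of H, computed once per grouping from the 1,680 distinct assignments
of nine ranks to three groups of three: a perfectly stage-ordered gene
reaches p = 1296/362880 ≈ 0.0036 < 0.01. This resolves a real
small-sample artifact, not a tuning choice. At the 11-group level (9 per
group) the chi-square approximation is adequate though conservative
(empirical type-I ≈ 0.002-0.008 at alpha 0.01); the three-group screens on
33 samples per group are well calibrated (≈ 0.01).

Headline percentages — plastic genes as a share of the average modulated
count and of the array content — are plain printed-count arithmetic,
exposed as `plasticity_rates()`.

### SAM

Significance Analysis of Microarrays is implemented in its original form:
per-gene moderated statistic $d = r/(s + s_0)$, where $r$ is the mean
difference (two-class) or the standardized square-root between-group sum
of squares (multiclass; it reduces to $|d|$ of the two-class form at two
groups), $s$ the matching pooled standard error, and $s_0$ a fudge factor
chosen on a grid of 5th-percentile steps of $s$ to minimize the
coefficient of variation of window-wise MAD of $d$ across $s$ windows.
Expected order statistics come from label permutations (all distinct
relabellings are enumerated when fewer than the requested count — e.g. the
20 balanced assignments of a 3 vs 3 comparison), and the
threshold delta is the smallest observed departure whose estimated FDR
meets the target.

Two FDR estimates are tabulated. The classical estimate divides the
*median* permutation false-positive count by the called count and scales
by the null fraction $\pi_0$ (estimated from the central 50% of the
permutation $d$ distribution). The median, however, is exactly zero in
roughly half of null datasets whenever few genes are called — the observed
maximum $d$ exceeds the per-permutation maxima about half the time — so a
median-driven delta choice lets single noise genes through even at an FDR
target of 0.1%. Delta selection therefore uses the *mean* false-positive
count (a Storey-type E[FP] estimate), which is bounded below by
1/n_perms whenever anything is called and makes the stringent operating
point behave as intended: on pure-noise data the called set is empty in
effectively all runs. The median-based estimate is reported alongside in
the delta table (`fdr_median`).

### Harvest analysis and markers

The harvest (stage 3) analysis chains SAM multiclass across vineyards
(FDR 0.1%), a fold-change screen (≥ 2-fold in at least one
vineyard-to-vineyard comparison of vineyard means), a 1 − r sample
dendrogram cut into two vineyard groups at the highest merge, and a
pooled-variance t-test (alpha 0.05) between the groups. All fold changes
are log2-mean differences with thresholds converted via `log2()`; the
matrix is on the log2 scale throughout, so this is the only coherent
reading even though fold-change scale is often left unstated in this
literature.

Developmental markers are the SAM-multiclass (three stage groups,
vineyards as replication) ∩ ANOVA (alpha 0.01, Bonferroni over the SAM
set) stage-modulated genes, clustered into eight Pearson-metric k-means
profiles; clusters whose centroid stage means strictly increase or
decrease are kept, and within each direction the genes at or above the
95th percentile of |stage3 − stage1| are retained. The percentile is
computed per direction over the monotone-cluster genes. Pearson-metric
k-means standardizes each profile to zero mean and unit variance first,
the standard construction making squared Euclidean distance proportional
to 1 − r; constant profiles (where r is undefined) fall back to raw
Euclidean assignment with a warning.

### Constitutive reference genes

Per stage, genes *not* significant under either SAM multiclass across the
11 vineyards (FDR 0.1%) or one-way ANOVA (alpha 0.01) are constitutive at
that stage; the three per-stage sets are intersected and ranked by
standard deviation across the replicate-averaged samples of the full
design. The "lowest (99th percentile)" wording of this screen is read as
keeping the bottom 1% of SDs — the only reading consistent with published
set sizes of this procedure (76 of 6,927 ≈ 1.1%). The ANOVA here is
deliberately uncorrected: a liberal significance test makes the
*non-significance* call, and hence the reference set, conservative.

### Latent-variable models

PCA and OPLS-DA both operate on UV-scaled (unit-variance autoscaled)
variables, observations = samples. PCA is an eigendecomposition of the
scaled covariance; per-component R²X values sum to 1 over the full rank.
The discriminant model is OPLS-DA in the single-block sense — NIPALS OPLS
of X against the centered class-indicator Y — which matches the common
"O2PLS-DA" usage for class models (the third digit of the
predictive+orthogonal+background component notation is always 0 here).
Q² comes from 7-fold class-stratified cross-validation with per-fold
re-estimation of both the UV scaling and the model. Overfitting is probed
by refitting under random label permutations (convention: 100), with
empirical p = (1 + #\{perm ≥ observed\})/(n_perms + 1) for both R²Y and
Q²; a strongly separable model yields the minimal p = 1/101. Loadings are
signed so each component's largest-magnitude element is positive, making
results reproducible across eigensolvers.

### Classification

`classify_genes()` merges the analysis outputs under the priority
plastic > marker_up/down > constitutive > modulated_nonplastic >
unclassified; multi-set genes are resolved by priority and logged in a
conflict table, so the final labelling is exhaustive and exclusive.

## The synthetic-data generator

`synthetic_spec()`/`generate_dataset()` emulate the study design —
defaults: 11 vineyards × 3 stages × 3 replicates, one season, 2,000 genes
— with planted gene classes and a truth table for parameter-recovery
testing. Choices, fixed once:

* Noise is Gaussian on the log2 scale (log-normal intensity noise, the
  standard microarray assumption), replicate sd 0.5; constitutive genes
  get their own tighter sd (0.1), since a reference-gene class is defined
  by *stability*, not merely absence of design effects — a separate field
  (`constitutive_noise_sd`) because one shared noise level cannot express
  that.
* Baselines are N(10, 1) log2 units; markers move ±2 log2 units per stage
  step; plastic genes get per-vineyard intercepts with sd 1 log2 unit;
  year effects (inert in one-season data) have sd 1.5.
* The low-signal artifact class is half the array (1,000 of 2,000 genes),
  mirroring real arrays of this kind where roughly half the probes sit at
  background; each such gene flips per sample between a background mode
  (2.5) and background + 2.5. The flips are per (gene, sample), not a
  per-gene baseline: the artifact being emulated is a probe fluctuating
  around the detection limit across hybridizations, and it is exactly this
  within-profile bimodality that the intensity filter detects. (Per-gene
  two-point baselines would be split by profile k-means into two separate,
  individually unimodal clusters, and no cluster would ever look bimodal.)
* With these defaults the pooled intensity histogram is itself bimodal
  (Sarle's b ≈ 0.58-0.60 > 0.555), as in the real data.

What the generator does **not** emulate: probe-level structure, dye or
spatial artifacts, correlated gene modules, heavy-tailed noise, or
metabolite data. Passing recovery tests therefore shows the pipeline's
statistics behave as designed under their own assumptions — not that real
arrays meet those assumptions.

## Reproducibility and problem sizes

Every stochastic step (generator, k-means restarts, SAM permutations,
cross-validation folds, permutation validation) is seed-driven;
identical inputs and seeds give byte-identical outputs, which the test
suite asserts end to end. The test and acceptance runs use desk-scale
sizes chosen to exercise every code path with comfortable statistical
margins: 2,000-gene designs for recovery and calibration, 300-500-gene
matrices for SAM null controls, 20-40-observation matrices for the
latent-variable checks, and full enumeration (≤ 1,680 assignments) for
exact small-n nulls.

## Known limitations

* The unimodal filter's termination rule depends on the bimodality
  criterion; on data whose low-signal component is weak or absent it
  returns a non-convergence flag and keeps all genes rather than guessing.
* The exact Kruskal-Wallis null assumes untied values; heavily tied rows
  fall back to the tie-corrected statistic against the untied null, a
  slight approximation at tiny n.
* Permutation FDRs for factor association permute whole vineyards, so
  with few vineyards the permutation space is small and estimates are
  coarse.
* OPLS-DA assumes more variables than informative components and at least
  two observations per class per fold; Q² is reported as NA when
  stratified folds cannot be formed.
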
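---
title: "Models and methods behind pathexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pathexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pathexpr implements a complete case/control transcriptomics workflow for
multi-region postmortem brain cohorts: covariate-adjusted negative-binomial
(NB) differential expression, cross-region concordance and DE-set
intersection, correlation-network co-expression modules scored per class
with a GSEA normalized enrichment score, Fisher-exact overrepresentation
with an Enrichr-style combined score, and a sparse multiple-kernel-learning
(MKL) classifier over pathway-restricted kernels with a replicated
stratified-split selection protocol. This vignette describes the models,
the defaults and why they were chosen, and what the synthetic cohorts do
and do not establish.

## The synthetic cohort generator

Every stage is validated against cohorts with planted, recorded ground
truth (`sim_config()`, `generate_pathways()`, `generate_metadata()`,
`generate_counts()`). The generator emulates the statistical structure of
a pooled multi-study brain cohort:

* **Counts.** `counts[g, s] ~ NB(mu_gs, alpha)` with
  `Var = mu + alpha * mu^2` and a single global dispersion
  (default `alpha = 0.1`, a typical bulk brain value; per-gene dispersion
  is estimated downstream regardless). The mean decomposes as
  `mu_gs = s_s * q_g * 2^(eta_gs)`: a log-normal library factor `s_s`
  (sd 0.3 on the log scale), a log-normal baseline `q_g` (median 100
  counts, log-sd 1.2), and log2-scale effects `eta_gs`.
* **Nuisance covariates.** Per-gene effects for source dataset (3 levels,
  sd 0.3), sex (sd 0.1), standardized age (sd 0.1), standardized
  postmortem interval (sd 0.05) and brain region (sd 0.2) — the
  confounding that the design formula must absorb.
* **Cohort shape.** Default region sample sizes follow a pooled
  three-study design of 457 samples over seven regions (216 control, 241
  case), with the dorsolateral prefrontal cortex largest (71/79). One
  region total is stated inconsistently in the source demographics table;
  the column totals force 19/24 for the ventral subiculum and that value
  is used. Ages and postmortem intervals are truncated normals around
  47.7 years and 24–26 h.
* **Condition effects.** Region-restricted planted log2 fold changes
  (`de_genes`; the default plants a hub gene at −1 in three regions plus
  a block of immediate-early-gene-like genes in the largest region, with
  |log2FC| spanning 0.5–2 — the true effect-size distribution is unknown,
  so this range is a documented free choice). Baselines of planted DE
  genes are pinned to the typical expression level: a gene drawn into the
  silent tail of the baseline distribution cannot carry a meaningful fold
  change, and the modeled analogue is a well-expressed transcription
  factor.
* **Co-expression modules.** Each module's genes load (uniform loadings
  0.8–1.2, the strong-module regime the module-recovery analyses assume)
  on a shared per-sample latent factor `u_s ~ N(±shift/2, latent_sd)`
  whose mean differs by condition (default shift −0.8: module activity
  lower in cases).
* **Pathways.** `n_pathways` gene sets drawn uniformly (overlap allowed);
  the member genes of the designated informative pathways receive an
  all-region condition effect of magnitude `informative_effect` with
  random sign, so only those kernels carry label information.

What the generator does **not** emulate: gene-wise dispersion
heterogeneity, correlated pathway membership structure, isoform effects,
sex-chromosome structure, or outlier samples. Passing the recovery tests
therefore shows the algorithms are correct and calibrated under the
modeled structure, not that real cohorts will behave as cleanly.

Seeding: one root seed fans out deterministically into child streams per
operation, so identical configurations reproduce byte-identical outputs
and any stage can be regenerated alone.

## Differential expression

The NB GLM with log link is fitted per gene with `log(size factor)`
offsets and fixed gene-wise dispersion:

* **Size factors** are median-of-ratios: the median over
  all-samples-positive genes of the count-to-geometric-mean ratio,
  rescaled to geometric mean 1.
* **Dispersions** are gene-wise method-of-moments estimates on normalized
  counts around an ordinary-least-squares fit of the design:
  `alpha_g = (s2_g - xi * mean_g) / mean_g^2` with `xi = mean(1/s_s)`,
  floored at 1e-8, with 50/50 log-space shrinkage toward a log-linear
  mean-dispersion trend (on by default in the pipeline driver: raw
  method-of-moments estimates are noisy at moderate n, and genes whose
  dispersion is underestimated by chance dominate the far p-value tail;
  the shrinkage restores tail calibration on signal-free cohorts). The
  full empirical-Bayes MAP
  treatment used by mainstream NB-DE packages is intentionally not
  replicated; per-gene p-values will differ from those tools, and
  correctness is established by simulation calibration (type-I error,
  p-value uniformity) instead of numerical parity.
* **Fitting** is iteratively reweighted least squares with weights
  `mu / (1 + alpha * mu)`, convergence at `max |delta beta| < 1e-6` or
  100 iterations; non-converged genes are excluded from the BH
  multiplicity count and reported.
* **Testing** is a Wald z on the condition coefficient (case vs control,
  control as reference, so downregulation in cases is negative), two
  sided, BH-adjusted over tested genes. No fold-change cut-off is
  applied. A minimum-expression prefilter (normalized mean >= 1, a
  deterministic and explainable stand-in for adaptive independent
  filtering) runs before testing.
* **Covariate coding:** numeric covariates (age, PMI) centered; factors
  treatment-coded with the lexicographically first level as reference;
  covariates constant within a region subset are dropped with a message;
  collinear designs fail loudly, naming the offending columns.

Per-region analyses use the design without the region term; the pooled
analysis adds it. `cross_region_spearman()` correlates log2FC profiles of
shared finite-estimate genes; `intersect_de_sets()` produces Venn cell
counts and the set of genes significant in every region with their signs.

A note on an invariance property: rescaling one sample's counts by a
constant is absorbed exactly by its size factor, but the resulting data
are no longer NB (the Poisson variance component scales linearly, the
data quadratically), so Wald statistics are only asymptotically
invariant; the tests assert near-invariance rather than bit equality.

## Co-expression modules and class-wise NES

Input expression is `log2(normalized counts + 1)`; the variance filter,
network construction and scoring operate on that scale.

* **Variance filter.** Per-gene variances are modeled as draws from a
  scaled chi-square, `var_g ~ scale * chisq(df)/df`, with scale and df
  fitted from the variances' median and MAD
  (`df = 2 (median/MAD)^2`, scale anchored to the chi-square median).
  Robust location/spread keeps genuinely high-variance genes from
  inflating the null they are tested against; on iid noise about 10% of
  genes pass the default `p < 0.1`. A per-gene mean scaling was
  considered and rejected: on log expression it couples the statistic to
  baseline abundance and systematically misses high-expression module
  genes.
* **Soft threshold.** Smallest power with scale-free fit R^2 >= 0.8
  *and* mean connectivity >= 1. The connectivity proviso matters: as the
  power grows the network empties and the fit index creeps upward
  spuriously, so an unconstrained "best fit" rule degenerates to the
  largest candidate. When no power qualifies (common for small,
  strongly modular desk-scale networks, which are simply not scale
  free), the sample-size power convention for unsigned networks is used
  (6 for >= 40 samples, 7/8/9 below).
* **Modules.** Unsigned adjacency `|cor|^beta`, topological-overlap
  dissimilarity, average-linkage hierarchical clustering, static tree cut
  at height 0.99 (uncorrelated genes sit at dissimilarity ~1 and remain
  singletons); clusters below `min_module_size` (default 30; 10 in
  desk-scale analyses) are left unassigned.
* **Class-wise NES.** Genes are z-scored across all samples; each class
  ranks genes by its mean z (for two balanced classes the two rankings
  are exact mirrors, which is why enrichment scores come out almost
  antisymmetric between classes). The enrichment score is the weighted
  Kolmogorov-Smirnov running sum (hit weight `|score|^1`); the null is
  size-matched random gene sets (a gene-label permutation null — cheap,
  seeded, and matched to the gene-set question being asked, rather than a
  sample-permutation null); `NES = ES / mean |null ES|` over same-sign
  nulls, p from the same-sign tail with the +1 correction, BH across
  modules within class. A set covering the whole universe has no misses
  and is scored +1 by convention. Pearson correlation is the default
  network correlation (the original analysis tool does not document its
  choice); Spearman is available.

## Overrepresentation and the combined score

`fisher_ora()` forms the standard 2x2 table against the background
universe (pathways first intersected with the background) and computes
the one-sided enrichment p as the hypergeometric upper tail. Odds ratios
use the cross-product with a Haldane 0.5 correction on zero cells
(flagged). The combined score is `-ln(p) * z`, where z measures how much
better the pathway's p-value rank is than expected for a random query of
the same size, estimated by seeded resampling of random queries
(default 200 draws); negative products floor at zero. A documented
fallback (`score_mode = "logOR"`) uses `log(OR)` as the deviation term.
The background defaults to all genes surviving the expression prefilter —
web enrichment services use library-internal backgrounds that are not
reproducible here, so tabulated scores from such services are not
comparable value-for-value. The top-pathway table also yields a gene-gene
co-occurrence edge list (weight = number of top pathways containing both
genes) and the count of query genes absent from every pathway.

## Pathway MKL

* **Preprocessing.** `log2(x + 1)`, stratified 80/20 split preserving the
  class ratio exactly, per-gene z-normalization fitted on the training
  samples only and applied unchanged to the test samples.
* **Kernels.** One Gaussian kernel per pathway on the pathway's expressed
  genes (>= 3 required), bandwidth `sigma^2 = ` mean squared pairwise
  training distance — a standard heuristic chosen because the original
  study does not document its kernel family or bandwidth; this divergence
  is deliberate and recorded.
* **MKL.** `K_eta = sum_m eta_m K_m` with `eta` on the simplex. Fit by
  alternating (a) the soft-margin SVM dual on `K_eta` (via kernlab's SMO;
  labels coded so positive decisions mean the case class) and (b) the
  multiplicative update `eta_m <- eta_m * sqrt(a' K_m a)` renormalized to
  the simplex — block coordinate descent on the group-lasso-style primal,
  so the SVM objective is non-increasing across alternations (asserted in
  tests up to solver tolerance). The l1 constraint drives most weights to
  zero; weights below 1e-6 are clamped, and a pathway counts as selected
  when its weight exceeds 0.01.
* **Protocol.** Per replication: split, 4-fold stratified inner CV over
  `C in 10^(-2..2)` (ties to the smallest C), final fit on the full
  training set, Mann-Whitney AUC on the test set. Replication r uses
  child seed `root + r` so any replication can be re-run exactly.
  Selection frequency = fraction of replications with weight > 0.01;
  pathways at frequency >= 1/2 are reported informative. Inner-CV fits
  use looser iteration caps (20 alternations, SMO tolerance 1e-4) than
  the final fits — the C ranking is insensitive to the optimization tail,
  and this keeps the replicated protocol tractable on one CPU.

## Numerical choices and degenerate inputs

Zero-variance genes: z-scores set to 0 (ranking), unit variance
substituted (MKL normalization), excluded before correlation (networks).
Non-PSD combined kernels get a 1e-8 diagonal jitter (flagged). A
single-class region or fold is an explicit error (regions with one
condition cannot be tested; CV folds are re-drawn). Zero p-values in the
combined score clamp to the smallest positive double. All thresholds the
pipeline exposes — DE padj 0.05, module padj 0.1, filter p 0.1, kernel
weight 0.01 — are configuration fields with those defaults.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run at desk scale, chosen so each
recovery question is answered with adequate replication: calibration
cohorts of 1000 genes x 60 samples (50 replicates), hub recovery on
800-gene seven-region cohorts (25 replicates), module recovery on
500-gene x 80-sample cohorts (20 replicates), and MKL on 600-gene
x 200-sample cohorts with 30 pathways (20 replications; the
acceptance script uses 10). Oracle comparisons are exhaustive at small
sizes (all hypergeometric tables with background <= 25; all subsets of
ranked universes <= 12).

## Known limitations

* NB inference uses plug-in method-of-moments dispersions; at very small
  sample sizes the Wald test is mildly anti-conservative compared with
  exact or shrinkage-based approaches.
* The module detector's static tree cut is deliberately simple; adjacent
  modules driven by correlated latent factors can merge, and weak modules
  below the cut height are missed.
* The combined-score z is a resampling estimate; its scale depends on the
  collection and background, so scores are comparable within one analysis
  only.
* MKL weights are not unique when kernels are highly correlated; the
  symmetric initialization and deterministic update make results
  reproducible, but near-duplicate pathways can share weight and dilute
  each other's selection frequency.
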
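---
title: "Methods: signature scoring, consensus forest clustering and treatment-predictive models"
author: "sigForest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scoring, consensus forest clustering and treatment-predictive models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigForest)
```

# The analysis this package implements

Metastatic triple-negative breast cancer (TNBC) trials that randomize
between a platinum (carboplatin) and a taxane (docetaxel) pose a biomarker
question: do transcriptional markers of DNA-damage-response (DDR)
deficiency predict platinum benefit, and do markers of immune infiltration
predict taxane benefit? sigForest implements the full analytical chain for
that question on bulk RNA-seq from archival primary tumours:

1. score ~30 DDR and immune signatures under eight published scoring
   schemes (`scoreSignatures`);
2. test each score's association with objective response (logistic
   regression per arm, treatment interaction) and progression-free
   survival (restricted-mean-survival regression) — `associationScan`;
3. integrate significant scores with pathologist TILs and BRCA1/2
   genotype into patient subgroups by consensus conditional-inference-
   forest clustering (`consensusCluster`);
4. characterize the subgroups with module scores and per-cluster per-arm
   response tables (`characterizeClusters`).

Because the motivating trial data are controlled-access, the package
ships a synthetic cohort generator (`generateCohort`) that emulates the
statistical structure the analysis assumes, so every stage is exercised
end to end by the test suite without any download.

# Scoring schemes

All schemes operate on a gene-by-sample FPKM-scale matrix. Schemes based
on log2 expression use `log2(x + pseudocount)` with a default pseudocount
of 1 (configurable); no pseudocount is published for these signatures, and
+1 keeps zero FPKM at score 0 while avoiding log(0).

| scheme | operation | example signature |
|---|---|---|
| `mean_centered` | per-gene mean-centring, then the mean over signature genes | CIN70 |
| `weighted_normalized` | per-sample division by the geometric mean of normalization genes, log2, per-gene median-centring, optional clipping to boundaries, weighted sum + bias | PARPi7 |
| `nearest_centroid` | Spearman correlation against centroid profiles; argmax label | TP53 status classifier |
| `negated_sum` | per-gene median-centring, negated sum | RPS |
| `median_log2` | median log2 value over signature genes | IGG cluster, 693 modules |
| `single_gene` | the gene's log2 value | PD-L1, CTLA4 |
| `first_pc` | first principal component of the gene-centred submatrix | CD8 TRM, CAF-S1 |
| `enrichment` | single-sample rank-weighted running-sum enrichment | ConsensusTME-style cell types |
| `linear_weighted` | weighted sum + bias on the linear FPKM scale | DDIR |

Decisions the published descriptions leave open:

* **Missing genes** are skipped with a logged warning; scoring errors out
  only when no signature gene remains. Archival FFPE panels routinely
  drop genes, so hard failure would be wrong, but silence would hide a
  changed gene set.
* **PC sign.** The first principal component is defined only up to sign;
  it is oriented so the score correlates positively with the per-sample
  mean of the signature genes, making "high score = high expression" hold
  by construction.
* **Nearest-centroid ties** go to the first centroid in registry order;
  constant sample profiles (Spearman undefined) are labelled
  `unclassifiable` and logged.
* **Enrichment.** Genes are ordered by decreasing expression (ties broken
  by matrix row order, so the statistic is deterministic); in-set ranks
  are weighted by `rank^alpha` with `alpha = 0.25` by default; raw
  statistics are min–max normalised across samples within each set. The
  average score is the mean over cell-type sets with fibroblast sets
  excluded (they are reported separately, as fibroblast content is not an
  immune quantity); the exclusion pattern is configurable.
* **Cohort dependence.** Mean and median centring make scores functions
  of the full sample set: adding one sample can move every score. This is
  intrinsic to the published schemes; the per-cohort recomputation is the
  default and the only mode implemented.
* **DDIR input scale.** Linear weighted scores consume raw FPKM, unlike
  the log2-based schemes; the input scale is a per-signature registry
  field (`inputScale`).
* **Top-marker selection** (`selectTopGenes`) filters strictly
  (`lfc > 1`, `fdr < 0.01`), caps at 50 by descending fold change, and
  breaks ties by ascending FDR then lexicographic gene id, so the
  selected set is reproducible.

# The synthetic cohort generator

`cohortConfig()` defaults are the package's standing description of the
cohort it emulates: 186 primary tumours, 2,000 genes, four planted
phenotype clusters (70/60/36/20) — immune-high, immune-low/proliferative,
fibroblast/RPS-high, and DDR-deficient. Expression is generated on the
log2(x+1) scale as

```
log2 value = gene baseline + block latent(sample) + N(0, noiseSd)
```

and back-transformed with `2^x − 1`, floored at 0 to keep FPKM
non-negativity. Gene baselines are N(3, 1.5²) in log2 units; block latents
are the planted per-cluster shifts (pattern magnitude `shiftScale`,
default 2 log2 units) plus within-cluster spread of SD 0.5; residual noise
SD defaults to 1. The `rps` gene block co-varies with the `cin70` block so
that the *negated* RPS score correlates negatively with CIN70, matching
the reported sign structure; TILs are logit-normal and positively coupled
to the immune latent.

Outcomes: treatment is assigned by 1:1 complete randomization (the trial
design); response follows a per-arm logistic model on the standardized
block latents with intercepts `qlogis(0.31)`/`qlogis(0.34)` (the arms'
overall response-rate scale) and default coefficients immune +0.5
log-odds/Z under docetaxel only and CIN70 +0.6 (carboplatin) / −0.3
(docetaxel) — free parameters of the generator, since no reusable
odds-ratio effect sizes are published; PFS is exponential with a 4-month
baseline median, log-hazard effects immune −0.2 and CIN70 +0.15 per
Z-unit, and independent uniform censoring calibrated to a 20% baseline
censoring fraction. A fraction 13/186 of patients receives a paired
recurrence sample whose block latents are shifted by +0.36 log2 units on
the CIN70 block (the reported primary-to-recurrence CIN70 change) with
fresh residual noise.

What the generator does *not* emulate: read-level sequencing noise,
batch/site effects, gene–gene correlation beyond the block structure,
non-exponential hazards, or informative censoring. Passing tests
therefore demonstrate correctness of the machinery under the assumed
model, not robustness to real-data artefacts. One numerical caveat: the
floor at 0 makes planted log2 shifts slightly inexact for genes whose
baseline is near zero; tests of exact shift recovery pin baselines well
above the floor, and cohort-level analyses are insensitive to the ~0.02
log2 bias involved.

# The unsupervised conditional-inference forest

No installed package provides conditional-inference-forest clustering,
so the construction is implemented here (C++ core in `src/forest.cpp`):

* A synthetic contrast set is built by independently permuting each
  feature column; trees discriminate real from contrast rows (the classic
  unsupervised-forest device — class labels encode "joint distribution
  vs. product of marginals").
* Splits are chosen by an association test between candidate feature and
  class label: the asymptotic permutation z-test for continuous features
  and chi-square for categoricals, with Bonferroni correction over the
  `mtry` candidates and a stopping level `alpha = 0.05`. Categorical
  features are handled natively (levels ordered by class rate, then
  scanned as ordered — the classical exact shortcut for binary targets).
* **Root exemption.** By construction the contrast matches every
  feature's *marginal* distribution, so the root association test has no
  power and a literal stopping rule at the root reduces almost every tree
  to a stump. The root split is therefore exempt from the stopping rule —
  the same spirit as forests grown with the stopping criterion disabled —
  while deeper nodes, where conditioning creates real signal, apply
  `alpha` as stated.
* Proximity(i, j) is the fraction of trees in which samples i and j share
  a terminal node; the dissimilarity is `1 − proximity`. Defaults: 500
  trees, `mtry = ceiling(sqrt(p))`, `minsplit = 20`, `minbucket = 7`,
  maximum depth 30. Everything is deterministic given the seed.

# Consensus clustering and the choice of k

`consensusCluster` runs 100 repetitions by default; each draws
`ceiling(0.8 p)` features without replacement, computes the forest
dissimilarity, and partitions **all** samples (subsampling is over
features, so consensus needs no co-inclusion normalization) by
average-linkage agglomeration at every candidate k. Samples are presented
to the agglomeration in a seeded random order and mapped back, so
tie-breaking cannot manufacture consensus on structureless inputs.

The consensus matrix at k holds co-clustering frequencies. Per k the area
under the empirical CDF of the off-diagonal entries is computed
(trapezoid rule) and the delta area is the relative increase over k−1
(floored at 0; `delta(k_min) = area(k_min)`), so delta areas are
non-negative by construction.

**Selection.** The paper-style procedure chooses k by *examination* of
the consensus matrices together with the delta-area curve. The automated
rule codifies both parts: a candidate k qualifies when its delta area
exceeds the threshold (default 0.05) *and* its consensus matrix passes
examination — the final partition is not dominated by one cluster holding
more than 80% of samples (the degenerate giant-core signature of
structureless data under agglomerative partitioning), and the proportion
of ambiguous clustering (PAC: entries strictly between 0.1 and 0.9) is at
most 0.5. The selected k is the largest qualifying candidate; if none
qualifies, the smallest candidate is returned with a warning that the
data may lack cluster structure. In measurements during development,
pure-noise feature tables show PAC of 0.85–0.99 at every k while
structured cohorts stay at or below ~0.4 (near 0 at the true k), so the
0.5 ceiling discriminates with a wide margin on both sides. The full
curve is always stored so users can override the automated choice.

Tiny clusters are kept, not merged (a minimum-size warning is logged):
real cohorts legitimately contain clusters of a handful of tumours.
Final labels come from average-linkage clustering of `1 − consensus`,
with cluster ids ordered by decreasing size.

Two practical notes. First, consensus results are exactly reproducible
for a fixed seed; under sample reordering they agree up to Monte-Carlo
noise (the RNG stream is tied to row order), comparable to the agreement
between two seeds. Second, `deterministicBase = TRUE` reuses one
repetition seed throughout, which with `featureFrac = 1` makes every
repetition identical and the consensus entries exactly 0/1 — useful for
testing the plumbing.

# Association statistics

Continuous biomarkers are Z-scored once on the full analysis cohort
before any arm subsetting, so per-arm effects share a scale and are
comparable across biomarkers.

* **Objective response**: univariable logistic regression per arm; the
  estimate is the log-odds ratio per Z-unit with Wald CI and two-sided p.
  Complete or quasi-complete separation is detected (fitted probabilities
  at 0/1 or runaway coefficients) and flagged with no finite estimate
  reported, rather than returning a divergent number.
* **Treatment interaction**: `response ~ z * arm`, two-sided Wald p for
  the product term by default; a likelihood-ratio switch is provided
  since the published analysis does not state which was used.
* **PFS**: restricted-mean-survival (RMST) regression via
  pseudo-observations — the jackknife leave-one-out transform of the
  Kaplan–Meier restricted mean at horizon tau, regressed linearly on the
  biomarker with HC1 robust standard errors. Pseudo-observations were
  chosen over IPCW because they handle covariates and interactions in
  one linear framework, matching a "linear regression of restricted mean
  PFS"; with no censoring they reduce exactly to `min(T, tau)`. The
  default tau is the minimum over analysis arms of the largest observed
  time — the standard identifiability-preserving choice, as no horizon is
  published.
* **Descriptive tests**: Wilcoxon rank sum (exact permutation enumeration
  for combined n ≤ 10, valid under ties; tie-corrected normal
  approximation with continuity correction otherwise), Kruskal–Wallis
  with Dunn post hoc z from pooled ranks (unadjusted by default, matching
  the exploratory analysis; Holm/BH switches available), Fisher exact
  2×2 (conditional two-sided p; sample odds ratio with a flagged Haldane
  +0.5 correction when a cell is zero), pairwise-complete Spearman
  matrices with flagged undefined cells, and paired t tests for
  primary-to-recurrence changes (zero-variance differences return the
  mean change with an undefined, flagged p).
* **Timepoint model for external paired datasets**: a Gaussian random-
  intercept model `score ~ timepoint + (1 | patient)` fitted by REML
  (lme4), accommodating patients with several metastatic samples; the
  fixed timepoint effect carries a two-sided Wald p. A singular patient
  variance collapses to ordinary regression and is flagged. In balanced
  one-sample-per-timepoint designs the estimate equals the paired mean
  difference exactly.

Multiple-testing adjustment is off by default, matching the exploratory
character of the analysis; `p.adjust` methods can be switched on.

# Pipeline and reproducibility

`runPipeline` chains reading/validation (expression TSV, clinical CSV,
YAML signature registry, optional GMT module sets), scoring, Z-scoring,
the association scan (overall plus prior-chemotherapy and
chemotherapy-naive subgroups; subgroups below `minSubgroupN = 15` samples
are skipped with a warning — small-subgroup models are exactly the ones a
cautious analysis declines to present), clustering-feature selection (any
univariable p < alpha in any arm/subgroup/endpoint, plus TILs and BRCA
status), consensus clustering, and characterization (module rows ordered
by average-linkage clustering, samples grouped by cluster — supervised in
the sense that samples never cross cluster boundaries). Every stage
writes CSV; a manifest records md5 checksums, and reruns with the same
config and seed are byte-identical. All randomness flows from the single
config seed.

# Problem sizes used by the checks

The test suite and `scripts/acceptance.R` exercise, as the package's
standing verification conditions: scheme-by-scheme oracle equivalence on
50 random 10-gene × 8-sample matrices (tolerance 1e−8); planted-cluster
recovery on 200-sample, 2,000-gene cohorts with shift/noise 3 under 100
repetitions × 80% features across 10 seeds; null calibration of each test
family at n = 200 with 1,000 replicates (acceptance band 3.5–6.5% at
alpha 0.05); parameter recovery at n = 400 with 500 replicates; and
full-pipeline determinism on a 60-sample cohort.

# Known limitations

* The forest RNG ties to sample order, so consensus equivariance under
  reordering is statistical, not exact.
* The delta-area/PAC selection rule is an automated stand-in for visual
  examination; for borderline structure users should inspect
  `cdfAreaCurve()` and the consensus matrices directly.
* Signature content (weights, centroids, boundaries) is registry input;
  the package validates structure, not biology. The synthetic registry's
  weights and centroids are labelled synthetic stand-ins, not published
  values.
* Identifiers must match between matrix and registry; there is no
  ortholog/alias mapping, only a missing-gene report.
* RMST pseudo-observation regression assumes censoring independent of
  covariates (otherwise IPCW-style corrections would be needed).
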
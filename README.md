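# sigForest

Transcriptional signature scoring, consensus conditional-inference-forest
clustering, and treatment-predictive biomarker statistics for randomized
oncology cohorts — built for the metastatic triple-negative breast cancer
(TNBC) setting where the question is whether DNA-damage-response (DDR)
markers predict platinum benefit and immune markers predict taxane
benefit.

## What it does

**Signature scoring.** `scoreSignatures()` evaluates a declarative
registry of signatures on a gene-by-sample FPKM matrix under eight
published scheme families: mean-centred mean (CIN70-style), geometric-mean
normalised weighted scores (PARPi7-style), nearest-centroid classification
by Spearman correlation (TP53-status-style), negated median-centred sums
(RPS-style), median log2 module scores, single-gene log2 markers, first
principal components (cell-type/CAF-style), single-sample rank-weighted
enrichment (ConsensusTME-style), and linear weighted scores on the FPKM
scale (DDIR-style).

**Subgroup discovery.** `consensusCluster()` integrates Z-scored
signatures, pathology TILs and BRCA1/2 genotype through an unsupervised
conditional-inference forest (association-test splits against a
permuted-column synthetic contrast; proximity = terminal-node
co-membership), repeated 100× over 80% feature subsamples. The number of
clusters comes from the consensus CDF delta-area curve, gated by an
automated examination of the consensus matrices (degenerate-partition and
ambiguity checks).

**Predictive statistics.** Per-arm logistic models of objective response
with separation flags, treatment×biomarker interaction tests,
restricted-mean-survival (RMST) regression of PFS via jackknife
pseudo-observations with robust errors, plus the descriptive toolkit
(exact/tie-corrected Wilcoxon, Kruskal–Wallis with Dunn post hoc, Fisher
exact 2×2, Spearman matrices, paired t, and a random-intercept timepoint
model for paired primary/recurrence designs).

**Synthetic cohorts.** `generateCohort()` draws TNBC-like cohorts with
planted cluster structure (correlated immune and DDR signature blocks),
arm-specific response effects, exponential PFS with censoring, TILs
coupled to the immune block, and paired recurrence samples with planted
log2 shifts — so the whole pipeline is testable with no external data.

In the core model, the response probability for patient *i* in arm *a*
follows logit p_i = α_a + Σ_b β_{b,a} z_{b,i} over standardized biomarker
scores z; the RMST regression estimates E[min(T, τ)] = γ0 + γ1 z in
months per Z-unit via pseudo-observations on the Kaplan–Meier functional.

## Worked example

```r
library(sigForest)

cfg <- cohortConfig(seed = 42L)        # 186 samples, 4 planted clusters
co  <- generateCohort(cfg)             # SummarizedExperiment ("fpkm")
reg <- generateSignatureRegistry(cfg)  # one signature per scheme family
scores <- scoreSignatures(co, reg)
clin   <- clinicalTable(co)
z      <- zscoreColumns(scores)

fitLogisticORR(z$IGG_cluster, clin$response,
               subset = clin$arm == "docetaxel",
               biomarker = "IGG_cluster", arm = "docetaxel")
#>     biomarker subgroup       arm estimate    ci_low  ci_high          p  n
#> 1 IGG_cluster      all docetaxel 1.033977 0.4995378 1.568417 0.00014948 93
```

The immune score carries about +1.03 log-odds of response per Z-unit
under docetaxel, and the effect differs between arms (interaction
p = 3e-04) — the generator's planted immune–taxane effect, recovered:

```r
testInteraction(z$IGG_cluster, clin$response, clin$arm)
#>   biomarker subgroup         arm estimate    ci_low  ci_high            p   n
#> 1         z      all interaction 1.230562 0.5610077 1.900116 0.0003155563 186
```

Clustering the feature table (signatures + TILs + BRCA status):

```r
feats <- z[vapply(z, is.numeric, logical(1))]
feats$TILs <- as.numeric(scale(clin$tils))
feats$BRCA <- factor(clin$brca_status)
cc <- consensusCluster(feats, kRange = 2:6, seed = 42L)
cc
#> ConsensusResult: k in {2,3,4,5,6}, selected k = 5, 186 sample(s)
#>   cluster sizes: 70/61/36/18/1
#>   delta CDF area: k=2:0.490  k=3:0.212  k=4:0.116  k=5:0.054  k=6:0.015

responseRateTable(clusterLabels(cc), clin$arm, clin$response)
#>   cluster  n ... rate_carboplatin rate_docetaxel          p  flag
#> 1       1 70 ...         34.21053       62.50000 0.02994553
#> 2       2 61 ...         50.00000       18.18182 0.01327888
#> 3       3 36 ...         52.94118       21.05263 0.08191436
#> 4       4 18 ...         66.66667       22.22222 0.15343480
#> 5       5  1 ...        100.00000             NA         NA  too_small_to_assess
```

The immune-high cluster (1) responds better to docetaxel (62.5% vs
34.2%), the immune-low/proliferative cluster (2) better to carboplatin
(50.0% vs 18.2%), and a singleton split-off is flagged rather than
tested — the qualitative pattern the analysis is designed to detect. At
this moderate planted separation the delta-area rule keeps a fifth,
one-sample cluster; the full curve is returned so that call can be
overridden after inspection.

`runPipeline(pipelineConfig(...))` chains the same steps from files
(expression TSV, clinical CSV, YAML registry, optional GMT modules) to a
directory of CSV outputs with an md5 manifest; a thin command-line
wrapper lives at `inst/scripts/sigforest.R`. The methods vignette
(`vignettes/sigForest-methods.Rmd`) documents the models, defaults and
design decisions.

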
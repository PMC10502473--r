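# Synthetic TNBC-like cohort generator. Expression is generated on the
# log2(x+1) scale as gene baseline + per-sample block latent + Gaussian
# noise, then back-transformed with 2^x - 1 floored at 0 so values stay on a
# non-negative FPKM-like scale. Named gene blocks (immune, cxcl13, cin70,
# rps, caf, parpi, ddir, housekeeping) carry planted per-cluster mean shifts;
# the same latent drives TILs, response and PFS so downstream associations
# are recoverable by construction.

.defaultBlockPattern <- function() {
  # rows: blocks; cols: planted clusters
  # 1 immune-high, 2 immune-low/CXCL13+CIN70-high, 3 fibroblast/RPS-high,
  # 4 DDR-deficient. The rps gene block co-varies with cin70, so the
  # negated RPS *score* correlates negatively with CIN70 at the sample
  # level (high RPS score = low repair-gene expression).
  rbind(immune       = c(1, -1, -0.5, 0),
        cxcl13       = c(-1, 1, 0, 0),
        cin70        = c(0, 1, -1, 1),
        rps          = c(0, 1, -1, 0.5),
        caf          = c(-0.5, 0, 1, -0.5),
        parpi        = c(0, 0, -0.5, 1),
        ddir         = c(0.5, 0, -0.5, 1),
        housekeeping = c(0, 0, 0, 0))
}

.defaultBlockSizes <- c(immune = 60, cxcl13 = 20, cin70 = 70, rps = 4,
                        caf = 30, parpi = 7, ddir = 10, housekeeping = 7)

#' CohortConfig: synthetic cohort parameters
#'
#' @slot nSamples,nGenes,nClusters cohort dimensions.
#' @slot clusterSizes per-cluster sample counts, summing to `nSamples`.
#' @slot blockSizes named gene counts per signature block; blocks are laid
#'   out over the first `sum(blockSizes)` genes in order.
#' @slot blockShifts block-by-cluster matrix of mean shifts in log2 units.
#' @slot baselineMean,baselineSd mean and SD of per-gene log2 baselines.
#' @slot blockLatentSd within-cluster SD of the per-sample block latent.
#' @slot noiseSd residual log2 noise SD (> 0).
#' @slot responseModel list: `intercepts` (named log-odds per arm) and
#'   `coef` (named list block -> named per-arm log-odds per latent Z-unit).
#' @slot pfsModel list: `baselineHazard` (events/month), `coef` (named list
#'   block -> log-hazard per latent Z-unit), `censoringRate` in \[0,1).
#' @slot tilsModel list: `intercept` (logit scale), `slope` (per immune
#'   latent Z-unit, positive so TILs track the immune block), `sd`.
#' @slot pairedFraction fraction of patients with a recurrence sample.
#' @slot recurrenceShift named per-block log2 mean shift at recurrence.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(nSamples = "integer", nGenes = "integer",
                 nClusters = "integer", clusterSizes = "integer",
                 blockSizes = "numeric", blockShifts = "matrix",
                 baselineMean = "numeric", baselineSd = "numeric",
                 blockLatentSd = "numeric", noiseSd = "numeric",
                 responseModel = "list", pfsModel = "list",
                 tilsModel = "list", pairedFraction = "numeric",
                 recurrenceShift = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  if (sum(object@clusterSizes) != object@nSamples)
    msg <- c(msg, "clusterSizes must sum to nSamples")
  if (any(object@clusterSizes <= 0L))
    msg <- c(msg, "all cluster sizes must be positive")
  if (length(object@clusterSizes) != object@nClusters)
    msg <- c(msg, "length(clusterSizes) must equal nClusters")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (sum(object@blockSizes) > object@nGenes)
    msg <- c(msg, "block gene lists exceed nGenes")
  if (!identical(rownames(object@blockShifts), names(object@blockSizes)))
    msg <- c(msg, "blockShifts rows must match blockSizes names")
  if (ncol(object@blockShifts) != object@nClusters)
    msg <- c(msg, "blockShifts must have one column per cluster")
  cr <- object@pfsModel$censoringRate
  if (is.null(cr) || cr < 0 || cr >= 1)
    msg <- c(msg, "censoringRate must be in [0,1)")
  if (object@pairedFraction < 0 || object@pairedFraction > 1)
    msg <- c(msg, "pairedFraction must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic cohort configuration
#'
#' Defaults emulate the study conditions the generator is meant to stand in
#' for: 186 primary tumours, four planted phenotype clusters (immune-high,
#' immune-low/proliferative, fibroblast/RPS-high, DDR-deficient), log2
#' shifts of magnitude `shiftScale` against unit noise, arm-specific
#' response effects (immune benefit under docetaxel, CIN70 benefit under
#' carboplatin), exponential PFS with ~4-month median, and a +0.36 log2
#' CIN70-block shift in recurrences.
#'
#' @param nSamples,nGenes cohort dimensions.
#' @param clusterSizes per-cluster counts (must sum to `nSamples`).
#' @param shiftScale multiplier applied to the built-in unit block-shift
#'   pattern (log2 units); `shiftScale / noiseSd` is the planted
#'   shift-to-noise ratio.
#' @param blockSizes,blockShifts override the built-in blocks; `blockShifts`
#'   is block-by-cluster in log2 units (rows named like `blockSizes`).
#' @param baselineMean,baselineSd,blockLatentSd,noiseSd log2-scale
#'   generation parameters.
#' @param responseModel,pfsModel,tilsModel outcome models (see
#'   [CohortConfig-class]); pass `coef` entries of zeros for null cohorts.
#' @param pairedFraction,recurrenceShift paired-recurrence design.
#' @param seed RNG seed.
#' @return a validated [CohortConfig-class].
#' @export
cohortConfig <- function(nSamples = 186L, nGenes = 2000L,
                         clusterSizes = NULL, shiftScale = 2,
                         blockSizes = .defaultBlockSizes,
                         blockShifts = NULL,
                         baselineMean = 3, baselineSd = 1.5,
                         blockLatentSd = 0.5, noiseSd = 1,
                         responseModel = list(
                           intercepts = c(carboplatin = qlogis(0.31),
                                          docetaxel = qlogis(0.34)),
                           coef = list(
                             immune = c(carboplatin = 0, docetaxel = 0.5),
                             cin70 = c(carboplatin = 0.6, docetaxel = -0.3))),
                         pfsModel = list(
                           baselineHazard = log(2) / 4,
                           coef = list(immune = -0.2, cin70 = 0.15),
                           censoringRate = 0.2),
                         tilsModel = list(intercept = qlogis(0.15),
                                          slope = 0.8, sd = 0.7),
                         pairedFraction = 13 / 186,
                         recurrenceShift = c(cin70 = 0.36),
                         seed = 1L) {
  if (is.null(blockShifts)) {
    blockShifts <- .defaultBlockPattern() * shiftScale
    if (!identical(names(blockSizes), rownames(blockShifts)))
      stop("custom blockSizes require a matching blockShifts matrix")
  }
  nClusters <- ncol(blockShifts)
  if (is.null(clusterSizes)) {
    base <- c(70L, 60L, 36L, 20L)
    clusterSizes <- if (nClusters == 4L && nSamples == 186L) base else {
      sz <- rep(nSamples %/% nClusters, nClusters)
      sz[seq_len(nSamples %% nClusters)] <- sz[seq_len(nSamples %% nClusters)] + 1L
      sz
    }
  }
  rs <- setNames(numeric(length(blockSizes)), names(blockSizes))
  rs[names(recurrenceShift)] <- recurrenceShift
  new("CohortConfig", nSamples = as.integer(nSamples),
      nGenes = as.integer(nGenes), nClusters = as.integer(nClusters),
      clusterSizes = as.integer(clusterSizes), blockSizes = blockSizes,
      blockShifts = blockShifts, baselineMean = baselineMean,
      baselineSd = baselineSd, blockLatentSd = blockLatentSd,
      noiseSd = noiseSd, responseModel = responseModel,
      pfsModel = pfsModel, tilsModel = tilsModel,
      pairedFraction = pairedFraction, recurrenceShift = rs,
      seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d samples x %d genes, %d planted clusters (%s)\n",
              object@nSamples, object@nGenes, object@nClusters,
              paste(object@clusterSizes, collapse = "/")))
  cat(sprintf("  blocks: %s; noise SD %.2f log2; seed %d\n",
              paste(names(object@blockSizes), collapse = ", "),
              object@noiseSd, object@seed))
})

#' Gene identifiers of each signature block
#'
#' Blocks occupy the leading genes of the matrix in declared order.
#'
#' @param config a [CohortConfig-class].
#' @return named list of gene id vectors.
#' @export
blockGenes <- function(config) {
  ids <- sprintf("g%04d", seq_len(config@nGenes))
  ends <- cumsum(config@blockSizes)
  starts <- ends - config@blockSizes + 1
  out <- lapply(seq_along(ends), function(i) ids[starts[i]:ends[i]])
  names(out) <- names(config@blockSizes)
  out
}

.uniformCensorMax <- function(h0, rate) {
  # P(C < T) for T ~ Exp(h0), C ~ U(0, m): 1 - (1 - exp(-h0 m)) / (h0 m)
  if (rate <= 0) return(Inf)
  f <- function(m) 1 - (1 - exp(-h0 * m)) / (h0 * m) - rate
  stats::uniroot(f, c(1e-6, 1e6))$root
}

.drawExpression <- function(config, latent, clusterOf, baselines, sampleIds) {
  n <- length(sampleIds)
  blocks <- blockGenes(config)
  log2mat <- matrix(rnorm(config@nGenes * n, 0, config@noiseSd),
                    config@nGenes, n,
                    dimnames = list(names(baselines), sampleIds))
  log2mat <- log2mat + baselines
  for (b in names(blocks)) {
    idx <- match(blocks[[b]], names(baselines))
    log2mat[idx, ] <- sweep(log2mat[idx, , drop = FALSE], 2,
                            latent[, b], "+")
  }
  pmax(2^log2mat - 1, 0)
}

#' Generate a synthetic cohort
#'
#' Draws expression, clinical covariates and outcomes under the configured
#' model. Treatment arms are assigned by 1:1 complete randomization;
#' objective response follows the configured per-arm logistic model on the
#' standardised block latents; PFS is exponential with independent uniform
#' censoring; TILs are logit-normal, positively coupled to the immune
#' latent. Deterministic for a fixed `config@seed`.
#'
#' @param config a [CohortConfig-class].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"fpkm"`, clinical columns in `colData` (including the planted
#'   `true_cluster`), and a `truth` list in `metadata()` holding the latent
#'   matrix, the outcome coefficients used and the recurrence shifts.
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nSamples
  sampleIds <- sprintf("S%03d", seq_len(n))
  patientIds <- sprintf("P%03d", seq_len(n))
  geneIds <- sprintf("g%04d", seq_len(config@nGenes))
  clusterOf <- rep(seq_len(config@nClusters), config@clusterSizes)

  baselines <- setNames(rnorm(config@nGenes, config@baselineMean,
                              config@baselineSd), geneIds)
  # per-sample block latent: planted cluster shift + within-cluster spread
  blocks <- names(config@blockSizes)
  latent <- sapply(blocks, function(b)
    config@blockShifts[b, clusterOf] +
      rnorm(n, 0, config@blockLatentSd))
  rownames(latent) <- sampleIds

  fpkm <- .drawExpression(config, latent, clusterOf, baselines, sampleIds)

  zlat <- scale(latent)
  zlat[, apply(latent, 2, sd) == 0] <- 0

  arm <- sample(rep(c("carboplatin", "docetaxel"), length.out = n))
  rm <- config@responseModel
  eta <- rm$intercepts[arm]
  for (b in names(rm$coef)) eta <- eta + rm$coef[[b]][arm] * zlat[, b]
  response <- rbinom(n, 1, plogis(eta))

  pm <- config@pfsModel
  loghr <- rep(0, n)
  for (b in names(pm$coef)) loghr <- loghr + pm$coef[[b]] * zlat[, b]
  tEvent <- rexp(n, rate = pm$baselineHazard * exp(loghr))
  cmax <- .uniformCensorMax(pm$baselineHazard, pm$censoringRate)
  tCens <- if (is.finite(cmax)) runif(n, 0, cmax) else rep(Inf, n)
  pfsTime <- pmin(tEvent, tCens)
  pfsEvent <- as.integer(tEvent <= tCens)

  tm <- config@tilsModel
  tils <- 100 * plogis(tm$intercept + tm$slope * zlat[, "immune"] +
                         rnorm(n, 0, tm$sd))
  brca <- sample(c("BRCA1_mutated", "BRCA2_mutated", "BRCA1_methylated",
                   "wildtype", "uncertain"), n, replace = TRUE,
                 prob = c(0.118, 0.027, 0.124, 0.591, 0.140))
  priorChemo <- rbinom(n, 1, 0.387)

  clin <- S4Vectors::DataFrame(
    sample_id = sampleIds, patient_id = patientIds, arm = arm,
    response = response, pfs_time = pmax(pfsTime, 1e-6),
    pfs_event = pfsEvent, tils = tils, brca_status = brca,
    prior_chemo = priorChemo, timepoint = "primary",
    true_cluster = clusterOf, row.names = sampleIds)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = fpkm), colData = clin)
  S4Vectors::metadata(se)$config <- config
  S4Vectors::metadata(se)$truth <- list(
    trueCluster = setNames(clusterOf, sampleIds), latent = latent,
    baselines = baselines, responseCoef = rm$coef, pfsCoef = pm$coef,
    recurrenceShift = config@recurrenceShift)
  se
}

#' Clinical table of a cohort
#'
#' @param cohort a cohort `SummarizedExperiment`.
#' @return plain data.frame of the clinical columns.
#' @export
clinicalTable <- function(cohort) {
  as.data.frame(SummarizedExperiment::colData(cohort))
}

#' Signature registry matching a synthetic cohort
#'
#' Emits one or more [Signature-class] definitions per planted block, with
#' at least one signature of every scoring scheme so a single
#' [scoreSignatures] run exercises all of them. Weights, centroids and
#' boundaries are fixed synthetic stand-ins for published signature
#' content; all gene lists are drawn from the generated gene identifiers.
#'
#' @param config a [CohortConfig-class].
#' @return a [SignatureSet-class].
#' @export
generateSignatureRegistry <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  bg <- blockGenes(config)
  parpiW <- c(-0.08, 0.53, 0.10, 0.09, -0.35, 0.79, -0.52)[
    seq_along(bg$parpi)]
  ddirW <- round(sin(seq_along(bg$ddir)) / 4, 3)  # fixed mixed-sign weights
  centGenes <- c(bg$cin70[1:5], bg$caf[1:5])
  mutant <- config@baselineMean + c(seq(1.5, 0.3, length.out = 5),
                                    seq(-0.3, -1.5, length.out = 5))
  centroids <- cbind(mutant = mutant, wildtype = rev(mutant))
  rownames(centroids) <- centGenes
  SignatureSet(list(
    Signature("CIN70", "mean_centered", genes = bg$cin70),
    Signature("RPS", "negated_sum", genes = bg$rps),
    Signature("PARPi7", "weighted_normalized", genes = bg$parpi,
              weights = parpiW, normGenes = bg$housekeeping,
              boundaries = c(-2, 2)),
    Signature("TP53_classifier", "nearest_centroid", centroids = centroids),
    Signature("IGG_cluster", "median_log2", genes = bg$immune[1:15]),
    Signature("CD8_TRM_mitotic", "median_log2", genes = bg$immune[16:25]),
    Signature("PD_L1", "single_gene", genes = bg$immune[1]),
    Signature("CAF_S1", "first_pc", genes = bg$caf),
    Signature("CD4_CXCL13", "first_pc", genes = bg$cxcl13),
    Signature("T_cells_CD8", "enrichment", genes = bg$immune[26:45]),
    Signature("Fibroblasts", "enrichment", genes = bg$caf[1:20]),
    Signature("DDIR", "linear_weighted", genes = bg$ddir,
              weights = ddirW, bias = 0.1)))
}

#' Append paired recurrence samples to a cohort
#'
#' Selects `round(pairedFraction * n)` patients and generates one recurrence
#' sample each: the same per-patient block latent plus the configured
#' per-block recurrence shift (log2 scale, applied before back-transform)
#' and fresh noise. Recurrence samples share the patient id and clinical
#' outcomes of their primary, with `timepoint = "recurrence"`.
#'
#' @param cohort a cohort from [generateCohort].
#' @param config the same [CohortConfig-class] used to generate it.
#' @return extended `SummarizedExperiment` (primaries first, then
#'   recurrences).
#' @export
generatePairedRecurrence <- function(cohort, config) {
  stopifnot(is(config, "CohortConfig"))
  nPairs <- round(config@pairedFraction * config@nSamples)
  if (nPairs < 2) stop("pairedFraction * nSamples must be >= 2")
  truth <- S4Vectors::metadata(cohort)$truth
  set.seed(config@seed + 1L)
  pick <- sort(sample(config@nSamples, nPairs))
  sampleIds <- colnames(cohort)[pick]
  recIds <- sub("^S", "R", sampleIds)
  latent <- truth$latent[pick, , drop = FALSE]
  latent <- sweep(latent, 2, config@recurrenceShift[colnames(latent)], "+")
  rownames(latent) <- recIds
  fpkm <- .drawExpression(config, latent, NULL, truth$baselines, recIds)
  clin <- SummarizedExperiment::colData(cohort)[pick, ]
  clin$sample_id <- recIds
  clin$timepoint <- "recurrence"
  rownames(clin) <- recIds
  rec <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = fpkm), colData = clin)
  out <- SummarizedExperiment::cbind(cohort, rec)
  S4Vectors::metadata(out)$truth <- truth
  S4Vectors::metadata(out)$config <- config
  out
}
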
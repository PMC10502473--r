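# Consensus conditional-inference-forest clustering: per repetition a
# feature subsample -> unsupervised forest dissimilarity -> average-linkage
# partition; co-clustering frequencies form the consensus matrices whose
# CDF-area curve selects k.

.featureMatrix <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) >= 2L,
            ncol(features) >= 1L)
  if (anyDuplicated(names(features))) stop("feature names must be unique")
  isCat <- integer(ncol(features))
  nLev <- integer(ncol(features))
  X <- matrix(0, nrow(features), ncol(features),
              dimnames = list(rownames(features), names(features)))
  for (j in seq_along(features)) {
    x <- features[[j]]
    if (all(is.na(x))) stop(sprintf("feature '%s' is all-missing",
                                    names(features)[j]))
    if (is.numeric(x)) {
      X[, j] <- x
    } else {
      f <- factor(x)
      if (nlevels(f) > 64L) stop("categorical features limited to 64 levels")
      isCat[j] <- 1L
      nLev[j] <- nlevels(f)
      X[, j] <- as.integer(f) - 1L
    }
  }
  if (any(!is.finite(X))) stop("features must be finite and non-missing")
  list(X = X, isCat = isCat, nLev = nLev)
}

#' Unsupervised forest dissimilarity between samples
#'
#' Builds a conditional-inference-style forest that discriminates the real
#' samples from a synthetic contrast set in which every feature column is
#' independently permuted, with permutation-test split selection (Bonferroni
#' over the `mtry` candidates, stopping at `alpha`). The dissimilarity is
#' `1 - proximity`, where proximity is the fraction of trees in which two
#' samples share a terminal node. Continuous and categorical features are
#' handled natively.
#'
#' @param features data.frame, one row per sample (rownames = sample ids);
#'   numeric columns are continuous features, character/factor columns
#'   categorical.
#' @param nTrees number of trees (default 500).
#' @param alpha stopping level for the split association test.
#' @param mtry candidate features per split (default `ceiling(sqrt(p))`).
#' @param minsplit,minbucket minimum node size to attempt / accept a split.
#' @param seed integer seed; the forest is deterministic given it.
#' @return symmetric sample-by-sample matrix, zero diagonal, values in
#'   \[0,1\].
#' @export
forestDissimilarity <- function(features, nTrees = 500L, alpha = 0.05,
                                mtry = NULL, minsplit = 20L, minbucket = 7L,
                                seed = 1L) {
  fm <- .featureMatrix(features)
  if (all(apply(fm$X, 2, function(x) length(unique(x)) == 1L)))
    stop("constant feature table: no splits possible")
  n <- nrow(fm$X)
  p <- ncol(fm$X)
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(p)))
  set.seed(seed)
  synth <- apply(fm$X, 2, function(x) x[sample.int(n)])
  synth <- matrix(synth, nrow = n)
  D <- .cifDistance(rbind(fm$X, synth), fm$isCat, fm$nLev, nReal = n,
                    nTrees = as.integer(nTrees), alpha = alpha,
                    mtry = as.integer(mtry), minsplit = as.integer(minsplit),
                    minbucket = as.integer(minbucket), maxdepth = 30L,
                    seed = as.integer(seed))
  dimnames(D) <- list(rownames(features), rownames(features))
  D
}

.partitionDistance <- function(D, k, permSeed) {
  # average-linkage cut; samples are presented to hclust in a seeded random
  # order so that tie-breaking cannot manufacture consensus on
  # structureless (constant-distance) inputs, then mapped back
  n <- nrow(D)
  set.seed(permSeed)
  perm <- sample.int(n)
  hc <- hclust(as.dist(D[perm, perm]), method = "average")
  lab <- cutree(hc, k = k)
  lab[order(perm)]
}

.consensusCdfArea <- function(M) {
  x <- sort(M[upper.tri(M)])
  if (length(x) == 0L) return(0)
  grid <- sort(unique(c(0, x, 1)))
  cdf <- vapply(grid, function(g) mean(x <= g), numeric(1))
  sum(diff(grid) * cdf[-length(grid)])
}

#' Consensus clustering over feature subsamples
#'
#' Runs `nReps` repetitions; each draws `ceiling(featureFrac * p)` features
#' without replacement, computes the forest dissimilarity on them and
#' partitions all samples by average-linkage agglomeration at every `k` in
#' `kRange`. The consensus matrix at `k` holds the fraction of repetitions
#' co-clustering each sample pair (every repetition covers all samples,
#' since the subsampling is over features). CDF areas, delta areas and the
#' selected k (see [selectK]) are filled in, and the final partition at the
#' selected k is obtained with [assignClusters].
#'
#' @param features data.frame as in [forestDissimilarity].
#' @param kRange candidate numbers of clusters (within `[2, n - 1]`).
#' @param nReps repetitions (default 100).
#' @param featureFrac feature fraction per repetition (default 0.8).
#' @param nTrees trees per forest (default 500, matching
#'   [forestDissimilarity]; fewer trees blur the consensus CDF curve).
#' @param alpha split-test stopping level.
#' @param deltaAreaThreshold threshold for the automatic k selection.
#' @param seed root seed; repetition seeds derive from it.
#' @param deterministicBase if `TRUE`, every repetition reuses the same
#'   forest seed and tie-break order, so with `featureFrac = 1` all
#'   repetitions are identical and consensus entries are exactly 0 or 1.
#' @return a [ConsensusResult-class].
#' @export
consensusCluster <- function(features, kRange = 2:6, nReps = 100L,
                             featureFrac = 0.8, nTrees = 500L, alpha = 0.05,
                             deltaAreaThreshold = 0.05, seed = 1L,
                             deterministicBase = FALSE) {
  fm <- .featureMatrix(features)  # validation only
  n <- nrow(features)
  p <- ncol(features)
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stop("kRange must lie within [2, n_samples - 1]")
  if (featureFrac <= 0 || featureFrac > 1)
    stop("featureFrac must be in (0, 1]")
  nSub <- ceiling(featureFrac * p)
  set.seed(seed)
  repSeeds <- sample.int(2^30, nReps)
  if (deterministicBase) repSeeds <- rep(repSeeds[1], nReps)

  counts <- lapply(kRange, function(k) matrix(0, n, n))
  names(counts) <- as.character(kRange)
  perRep <- matrix(NA_integer_, n, nReps,
                   dimnames = list(rownames(features), NULL))
  for (r in seq_len(nReps)) {
    set.seed(repSeeds[r])
    fIdx <- sort(sample.int(p, nSub))
    D <- forestDissimilarity(features[, fIdx, drop = FALSE],
                             nTrees = nTrees, alpha = alpha,
                             seed = repSeeds[r])
    for (ki in seq_along(kRange)) {
      lab <- .partitionDistance(D, kRange[ki], permSeed = repSeeds[r] + ki)
      counts[[ki]] <- counts[[ki]] + outer(lab, lab, "==")
      if (ki == 1L) perRep[, r] <- lab
    }
  }
  consensus <- lapply(counts, function(M) {
    M <- M / nReps
    diag(M) <- 1
    dimnames(M) <- list(rownames(features), rownames(features))
    M
  })
  areas <- vapply(consensus, .consensusCdfArea, numeric(1))
  deltas <- numeric(length(kRange))
  deltas[1] <- areas[1]
  if (length(kRange) > 1L)
    deltas[-1] <- pmax(0, diff(areas) / head(areas, -1))
  candidateLabels <- lapply(seq_along(kRange), function(ki)
    assignClusters(consensus[[ki]], kRange[ki]))
  degenerate <- vapply(candidateLabels, .isDegeneratePartition, logical(1))
  ambiguous <- vapply(consensus, .pacScore, numeric(1)) > 0.5
  sel <- selectKFromCurve(kRange, deltas, deltaAreaThreshold,
                          degenerate | ambiguous)
  if (all(degenerate | ambiguous))
    warning("no candidate k shows crisp, non-degenerate consensus; ",
            "the data may lack cluster structure", call. = FALSE)
  labels <- candidateLabels[[which(kRange == sel)]]
  res <- new("ConsensusResult", kRange = kRange, consensus = consensus,
             cdfArea = unname(areas), deltaArea = deltas,
             selectedK = as.integer(sel), labels = labels,
             perRepLabels = perRep, seed = as.integer(seed))
  validObject(res)
  small <- table(labels)
  if (any(small < 5))
    warning(sprintf("cluster(s) below 5 samples kept: %s",
                    paste(names(small)[small < 5], collapse = ", ")),
            call. = FALSE)
  res
}

# the hallmark of structureless data under agglomerative partitioning is a
# giant core cluster with peeled-off outliers; such candidates are not
# evidence for their k
.isDegeneratePartition <- function(labels, domFrac = 0.8) {
  max(table(labels)) > domFrac * length(labels)
}

# proportion of ambiguous clustering: fraction of consensus entries that
# are neither clearly together (> hi) nor clearly apart (< lo); genuine
# structure at the right k gives near-0/1 consensus and PAC near 0
.pacScore <- function(M, lo = 0.1, hi = 0.9) {
  x <- M[upper.tri(M)]
  mean(x > lo & x < hi)
}

selectKFromCurve <- function(kRange, deltaArea, threshold = 0.05,
                             unqualified = rep(FALSE, length(kRange))) {
  above <- which(deltaArea > threshold & !unqualified)
  if (length(above) == 0L) return(kRange[1])
  kRange[max(above)]
}

#' Select the number of clusters from the CDF-area curve
#'
#' The area under the consensus CDF is computed per k (trapezoid rule over
#' the empirical CDF of the off-diagonal consensus entries); the delta area
#' is the relative increase over k-1 (floored at 0, with
#' `delta(k_min) = area(k_min)`). The selected k is the largest candidate
#' whose delta area exceeds `threshold` and whose consensus matrix passes
#' the codified matrix examination: the partition must not be degenerate
#' (dominated by a single giant cluster, the signature of structureless
#' data under agglomerative partitioning) and the proportion of ambiguous
#' clustering (PAC: consensus entries strictly between 0.1 and 0.9) must
#' not exceed 0.5. When no candidate qualifies the smallest k is returned
#' (with a warning from [consensusCluster]). The full curve is kept in the
#' result so the automatic choice can be overridden after inspection.
#'
#' @param result a [ConsensusResult-class].
#' @param threshold delta-area threshold (default 0.05).
#' @return the selected k (integer).
#' @export
selectK <- function(result, threshold = 0.05) {
  stopifnot(is(result, "ConsensusResult"), length(result@kRange) >= 2L)
  unqualified <- vapply(seq_along(result@kRange), function(ki) {
    M <- result@consensus[[ki]]
    .isDegeneratePartition(assignClusters(M, result@kRange[ki])) ||
      .pacScore(M) > 0.5
  }, logical(1))
  selectKFromCurve(result@kRange, result@deltaArea, threshold, unqualified)
}

#' Final partition of a consensus matrix
#'
#' Average-linkage hierarchical clustering of `1 - consensus`, cut at `k`;
#' label ids are reassigned in order of decreasing cluster size (ties by
#' first occurrence), so the output is invariant to sample input order up
#' to nothing -- identical inputs give identical labels.
#'
#' @param consensus symmetric consensus matrix in \[0,1\].
#' @param k number of clusters.
#' @return named integer vector of cluster labels in `1..k`.
#' @export
assignClusters <- function(consensus, k) {
  stopifnot(is.matrix(consensus), nrow(consensus) == ncol(consensus))
  hc <- hclust(as.dist(1 - consensus), method = "average")
  raw <- cutree(hc, k = k)
  sizes <- table(raw)
  newId <- rank(-as.vector(sizes), ties.method = "first")
  out <- as.integer(newId[match(raw, as.integer(names(sizes)))])
  names(out) <- rownames(consensus)
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 means identical partitions up to relabeling.
#' @export
ariIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(1)
  (sumij - expected) / (maxIdx - expected)
}
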
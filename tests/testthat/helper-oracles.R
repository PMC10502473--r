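# Fixtures and independent brute-force oracles for the scoring schemes.
# The oracles follow the written definitions step by step with explicit
# loops, independent of the vectorised implementations they check.

randomFpkm <- function(nGenes = 10, nSamples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(2^rnorm(nGenes * nSamples, 3, 1.5) - 1, nGenes, nSamples,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  pmax(m, 0)
}

oracleMeanCentered <- function(lg, genes) {
  sub <- lg[genes, , drop = FALSE]
  out <- numeric(ncol(sub))
  for (s in seq_len(ncol(sub))) {
    acc <- 0
    for (g in seq_len(nrow(sub)))
      acc <- acc + (sub[g, s] - mean(sub[g, ]))
    out[s] <- acc / nrow(sub)
  }
  setNames(out, colnames(sub))
}

oracleWeightedNormalized <- function(fpkm, genes, weights, normGenes,
                                     boundaries = NULL, bias = 0,
                                     pseudocount = 1) {
  lgMat <- matrix(0, length(genes), ncol(fpkm))
  for (s in seq_len(ncol(fpkm))) {
    gm <- prod(fpkm[normGenes, s] + pseudocount)^(1 / length(normGenes))
    for (g in seq_along(genes))
      lgMat[g, s] <- log2((fpkm[genes[g], s] + pseudocount) / gm)
  }
  out <- numeric(ncol(fpkm))
  for (s in seq_len(ncol(fpkm))) {
    acc <- bias
    for (g in seq_along(genes)) {
      v <- lgMat[g, s] - median(lgMat[g, ])
      if (!is.null(boundaries)) v <- min(max(v, boundaries[1]), boundaries[2])
      acc <- acc + weights[g] * v
    }
    out[s] <- acc
  }
  setNames(out, colnames(fpkm))
}

oracleNegatedSum <- function(lg, genes) {
  out <- numeric(ncol(lg))
  for (s in seq_len(ncol(lg))) {
    acc <- 0
    for (g in genes) acc <- acc + (lg[g, s] - median(lg[g, ]))
    out[s] <- -acc
  }
  setNames(out, colnames(lg))
}

oracleMedianLog2 <- function(lg, genes) {
  out <- numeric(ncol(lg))
  for (s in seq_len(ncol(lg))) out[s] <- median(lg[genes, s])
  setNames(out, colnames(lg))
}

oracleFirstPC <- function(lg, genes) {
  sub <- lg[genes, , drop = FALSE]
  centred <- sub
  for (g in seq_len(nrow(sub))) centred[g, ] <- sub[g, ] - mean(sub[g, ])
  ev <- eigen(t(centred) %*% centred, symmetric = TRUE)
  score <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
  if (cor(score, colMeans(sub)) < 0) score <- -score
  setNames(score, colnames(lg))
}

oracleEnrichment <- function(fpkm, genes, alpha = 0.25) {
  n <- nrow(fpkm)
  raw <- numeric(ncol(fpkm))
  for (s in seq_len(ncol(fpkm))) {
    ord <- order(fpkm[, s], decreasing = TRUE)
    orderedGenes <- rownames(fpkm)[ord]
    inSet <- orderedGenes %in% genes
    wts <- (n - seq_len(n) + 1)^alpha
    sumIn <- sum(wts[inSet])
    nOut <- n - sum(inSet)
    pin <- 0; pout <- 0; es <- 0
    for (i in seq_len(n)) {
      if (inSet[i]) pin <- pin + wts[i] / sumIn
      else pout <- pout + 1 / nOut
      es <- es + (pin - pout)
    }
    raw[s] <- es
  }
  rng <- range(raw)
  out <- if (diff(rng) == 0) raw else (raw - rng[1]) / diff(rng)
  setNames(out, colnames(fpkm))
}

oracleLinearWeighted <- function(fpkm, genes, weights, bias = 0) {
  out <- numeric(ncol(fpkm))
  for (s in seq_len(ncol(fpkm))) {
    acc <- bias
    for (g in seq_along(genes)) acc <- acc + weights[g] * fpkm[genes[g], s]
    out[s] <- acc
  }
  setNames(out, colnames(fpkm))
}

oracleCentroidCalls <- function(lg, centroids) {
  shared <- intersect(rownames(centroids), rownames(lg))
  calls <- character(ncol(lg))
  for (s in seq_len(ncol(lg))) {
    rho <- sapply(colnames(centroids), function(cl)
      cor(lg[shared, s], centroids[shared, cl], method = "spearman"))
    calls[s] <- colnames(centroids)[which.max(rho)]
  }
  setNames(calls, colnames(lg))
}

# small registry over a random matrix, one signature per scheme
tinyRegistry <- function(fpkm) {
  g <- rownames(fpkm)
  centroids <- cbind(A = seq_along(g[1:5]), B = rev(seq_along(g[1:5])))
  rownames(centroids) <- g[1:5]
  SignatureSet(list(
    Signature("mc", "mean_centered", genes = g[1:5]),
    Signature("wn", "weighted_normalized", genes = g[1:4],
              weights = c(0.5, -0.25, 1, 0.1), normGenes = g[6:9],
              boundaries = c(-1.5, 1.5)),
    Signature("nc", "nearest_centroid", centroids = centroids),
    Signature("ns", "negated_sum", genes = g[2:5]),
    Signature("md", "median_log2", genes = g[c(1, 4, 7)]),
    Signature("sg", "single_gene", genes = g[3]),
    Signature("pc", "first_pc", genes = g[1:6]),
    Signature("en", "enrichment", genes = g[c(2, 5, 8)]),
    Signature("lw", "linear_weighted", genes = g[1:3],
              weights = c(1, -1, 2), bias = 0.5)))
}

# planted-blob feature table for clustering tests: each blob carries its
# own marker features (shifted by sep), plus shared noise features, so the
# 80% feature subsampling has real diversity to draw on
blobFeatures <- function(nPerBlob = 20, nBlobs = 3, nMarkers = 3,
                         nNoise = 1, sep = 6, seed = 1) {
  set.seed(seed)
  nFeat <- nBlobs * nMarkers + nNoise
  n <- nBlobs * nPerBlob
  X <- matrix(rnorm(n * nFeat), n, nFeat)
  for (b in seq_len(nBlobs)) {
    rows <- ((b - 1) * nPerBlob + 1):(b * nPerBlob)
    cols <- ((b - 1) * nMarkers + 1):(b * nMarkers)
    X[rows, cols] <- X[rows, cols] + sep
  }
  df <- as.data.frame(X)
  names(df) <- sprintf("f%d", seq_len(nFeat))
  rownames(df) <- sprintf("b%d_%02d", rep(seq_len(nBlobs), each = nPerBlob),
                          rep(seq_len(nPerBlob), nBlobs))
  attr(df, "truth") <- rep(seq_len(nBlobs), each = nPerBlob)
  df
}

expect_scores_equal <- function(a, b, tol = 1e-8) {
  expect_equal(unname(a[names(b)]), unname(b), tolerance = tol)
}
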
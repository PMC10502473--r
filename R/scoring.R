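# Signature scoring schemes. All schemes that consume log2 expression take a
# gene-by-sample matrix already on the log2 scale (see log2Transform);
# weighted_normalized, enrichment and linear_weighted start from the raw
# FPKM-scale matrix because their normalisation is defined on that scale.

.checkExprMatrix <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample identifiers in expression matrix")
  if (any(!is.finite(expr)))
    stop("expression matrix contains non-finite values")
  invisible(expr)
}

.presentGenes <- function(genes, expr, signame, minPresent = 1L) {
  present <- genes[genes %in% rownames(expr)]
  missing <- setdiff(genes, present)
  if (length(missing))
    warning(sprintf("signature '%s': %d gene(s) absent from matrix: %s",
                    signame, length(missing),
                    paste(head(missing, 5), collapse = ", ")),
            call. = FALSE)
  if (length(present) < minPresent)
    stop(sprintf("signature '%s': fewer than %d of its genes present",
                 signame, minPresent), call. = FALSE)
  present
}

#' Log2-transform an FPKM-scale expression matrix
#'
#' @param expr non-negative gene-by-sample matrix.
#' @param pseudocount non-negative value added before taking log2. The
#'   default of 1 keeps zero FPKM at score 0 and avoids log(0).
#' @return matrix of `log2(expr + pseudocount)`.
#' @examples
#' m <- matrix(c(0, 7), 1, 2, dimnames = list("g1", c("s1", "s2")))
#' log2Transform(m)  # 0 and 3
#' @export
log2Transform <- function(expr, pseudocount = 1) {
  .checkExprMatrix(expr)
  if (any(expr < 0)) stop("expression values must be >= 0")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(expr == 0))
    stop("pseudocount = 0 with zero expression values: log2(0) undefined")
  log2(expr + pseudocount)
}

#' Mean-centred mean score (CIN70 scheme)
#'
#' Each present signature gene is centred to mean zero across samples; the
#' score is the mean of centred values over the signature genes, so the
#' cross-sample mean of the score is zero by construction.
#'
#' @param exprLog2 log2-scale gene-by-sample matrix.
#' @param sig a [Signature-class] with scheme `mean_centered`.
#' @return named numeric vector, one score per sample.
#' @export
scoreMeanCentered <- function(exprLog2, sig) {
  g <- .presentGenes(sig@genes, exprLog2, sig@name)
  sub <- exprLog2[g, , drop = FALSE]
  centred <- sub - rowMeans(sub)
  colMeans(centred)
}

#' Geometric-mean-normalised weighted score (PARPi7 scheme)
#'
#' Per sample, each signature gene is divided by the geometric mean of the
#' normalization genes, log2-transformed, median-centred per gene across
#' samples, optionally clipped to the signature's boundaries, and combined
#' as the weighted sum plus bias. Returned as a continuous score.
#'
#' @param expr raw FPKM-scale gene-by-sample matrix.
#' @param sig a [Signature-class] with scheme `weighted_normalized`.
#' @param pseudocount added to all values before forming ratios.
#' @return named numeric vector of scores.
#' @export
scoreWeightedNormalized <- function(expr, sig, pseudocount = 1) {
  missNorm <- setdiff(sig@normGenes, rownames(expr))
  if (length(missNorm))
    stop(sprintf("signature '%s': normalization gene(s) missing: %s",
                 sig@name, paste(missNorm, collapse = ", ")))
  keep <- sig@genes %in% rownames(expr)
  g <- .presentGenes(sig@genes, expr, sig@name)
  w <- sig@weights[keep]
  normVals <- expr[sig@normGenes, , drop = FALSE] + pseudocount
  if (any(normVals <= 0))
    stop(sprintf("signature '%s': non-positive normalization values",
                 sig@name))
  geo <- exp(colMeans(log(normVals)))
  ratio <- sweep(expr[g, , drop = FALSE] + pseudocount, 2, geo, "/")
  lg <- log2(ratio)
  centred <- lg - apply(lg, 1, median)
  if (length(sig@boundaries) == 2L)
    centred <- pmin(pmax(centred, sig@boundaries[1]), sig@boundaries[2])
  drop(crossprod(centred, w))[colnames(expr)] + sig@bias
}

#' Nearest-centroid classification by Spearman correlation (TP53 scheme)
#'
#' Each sample is correlated (Spearman) with every centroid profile over
#' the genes shared between matrix and centroids, and assigned the label of
#' the best-correlated centroid; ties go to the first centroid in declared
#' order. Samples with a constant profile over the shared genes are labelled
#' `"unclassifiable"`.
#'
#' @param exprLog2 log2-scale gene-by-sample matrix.
#' @param sig a [Signature-class] with scheme `nearest_centroid`.
#' @return list with `calls` (character per sample) and `correlations`
#'   (sample-by-centroid matrix).
#' @export
classifyNearestCentroid <- function(exprLog2, sig) {
  shared <- intersect(rownames(sig@centroids), rownames(exprLog2))
  if (length(shared) < 3L)
    stop(sprintf("signature '%s': only %d gene(s) shared with centroids; >=3 required",
                 sig@name, length(shared)))
  cent <- sig@centroids[shared, , drop = FALSE]
  sub <- exprLog2[shared, , drop = FALSE]
  labels <- colnames(cent)
  cors <- matrix(NA_real_, ncol(sub), ncol(cent),
                 dimnames = list(colnames(sub), labels))
  calls <- character(ncol(sub))
  for (s in seq_len(ncol(sub))) {
    x <- sub[, s]
    if (sd(x) == 0) {
      calls[s] <- "unclassifiable"
      next
    }
    rho <- suppressWarnings(cor(x, cent, method = "spearman"))
    cors[s, ] <- rho
    calls[s] <- labels[which.max(rho)]  # which.max: first wins on ties
  }
  if (any(calls == "unclassifiable"))
    warning(sprintf("signature '%s': %d constant-profile sample(s) unclassifiable",
                    sig@name, sum(calls == "unclassifiable")), call. = FALSE)
  names(calls) <- colnames(sub)
  list(calls = calls, correlations = cors)
}

#' Negated median-centred sum (RPS scheme)
#'
#' Each gene is median-centred across samples; the score is minus the sum of
#' the centred values over the signature genes.
#'
#' @inheritParams scoreMeanCentered
#' @param sig a [Signature-class] with scheme `negated_sum`.
#' @return named numeric vector of scores.
#' @export
scoreNegatedSum <- function(exprLog2, sig) {
  g <- .presentGenes(sig@genes, exprLog2, sig@name)
  if (length(g) < length(sig@genes))
    warning(sprintf("signature '%s': score computed over %d of %d genes",
                    sig@name, length(g), length(sig@genes)), call. = FALSE)
  sub <- exprLog2[g, , drop = FALSE]
  centred <- sub - apply(sub, 1, median)
  -colSums(centred)
}

#' Median log2 expression score (module-score scheme)
#'
#' @inheritParams scoreMeanCentered
#' @param sig a [Signature-class] with scheme `median_log2`.
#' @return named numeric vector: per sample, the median log2 value over the
#'   present signature genes.
#' @export
scoreMedianLog2 <- function(exprLog2, sig) {
  g <- .presentGenes(sig@genes, exprLog2, sig@name)
  apply(exprLog2[g, , drop = FALSE], 2, median)
}

#' Single-gene log2 score (checkpoint-marker scheme)
#'
#' @inheritParams scoreMeanCentered
#' @param gene one gene identifier (or a single-gene [Signature-class]).
#' @return named numeric vector: the gene's log2 value per sample.
#' @export
scoreSingleGene <- function(exprLog2, gene) {
  if (is(gene, "Signature")) gene <- gene@genes
  stopifnot(length(gene) == 1L)
  if (!gene %in% rownames(exprLog2))
    stop(sprintf("gene '%s' absent from expression matrix", gene))
  exprLog2[gene, ]
}

#' Select top differentially expressed genes for a cell type
#'
#' Strict filter `log_fold_change > lfcMin` and `fdr < fdrMax` for the
#' requested cell type, then the top `nTop` genes by descending fold change.
#' Ties at the cut are broken by ascending FDR, then lexicographic gene id,
#' so the selection is deterministic.
#'
#' @param de data.frame with columns `gene_id`, `log_fold_change`, `fdr`,
#'   `cell_type`.
#' @param cellType which cell type's markers to select.
#' @param lfcMin,fdrMax,nTop filter and cap parameters.
#' @return character vector of gene ids (possibly shorter than `nTop`).
#' @export
selectTopGenes <- function(de, cellType, lfcMin = 1, fdrMax = 0.01,
                           nTop = 50) {
  stopifnot(nrow(de) > 0,
            all(c("gene_id", "log_fold_change", "fdr", "cell_type") %in%
                names(de)))
  sub <- de[de$cell_type == cellType & de$log_fold_change > lfcMin &
              de$fdr < fdrMax, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning(sprintf("no genes survive the filter for cell type '%s'",
                    cellType), call. = FALSE)
    return(character(0))
  }
  ord <- order(-sub$log_fold_change, sub$fdr, sub$gene_id)
  head(sub$gene_id[ord], nTop)
}

#' First-principal-component score (cell-type / CAF scheme)
#'
#' The signature submatrix is centred per gene; the score is each sample's
#' coordinate on the first principal component (projection onto the leading
#' unit-norm gene loading vector), with the sign oriented so the score
#' correlates positively with the per-sample mean of the signature genes.
#'
#' @inheritParams scoreMeanCentered
#' @param sig a [Signature-class] with scheme `first_pc`.
#' @return named numeric vector of PC1 scores.
#' @export
scoreFirstPC <- function(exprLog2, sig) {
  g <- .presentGenes(sig@genes, exprLog2, sig@name, minPresent = 2L)
  if (ncol(exprLog2) < 3L) stop("first_pc scoring needs >= 3 samples")
  sub <- exprLog2[g, , drop = FALSE]
  centred <- sub - rowMeans(sub)
  if (all(abs(centred) < 1e-12))
    stop(sprintf("signature '%s': zero-variance submatrix", sig@name))
  sv <- svd(centred, nu = 1, nv = 1)
  score <- sv$d[1] * sv$v[, 1]
  names(score) <- colnames(sub)
  ref <- colMeans(sub)
  if (sd(ref) > 0 && cor(score, ref) < 0) score <- -score
  score
}

#' Single-sample rank enrichment scores (ConsensusTME-style scheme)
#'
#' Per sample and gene set, an ssGSEA-type running-sum statistic: genes are
#' ordered by decreasing expression (ties broken by matrix row order), the
#' in-set cumulative distribution is weighted by `rank^alpha` (rank from the
#' bottom, so the top gene carries weight `n^alpha`), the out-of-set CDF is
#' unweighted, and the statistic is the sum over ranks of their difference.
#' Raw statistics are min-max normalised across samples within each set
#' (left unchanged if constant). The average score is the mean over sets,
#' excluding sets whose name matches `excludeFromAverage` — fibroblasts are
#' kept out of the immune average by default.
#'
#' @param expr raw FPKM-scale gene-by-sample matrix (ranks are invariant to
#'   monotone transforms, so the log2 matrix gives identical results).
#' @param geneSets named list of gene id vectors.
#' @param alpha rank-weight exponent (default 0.25).
#' @param excludeFromAverage regular expression; matching set names are
#'   reported individually but excluded from the average score.
#' @return list with `scores` (sample-by-set matrix of normalised
#'   enrichment scores) and `average` (per-sample mean over non-excluded
#'   sets).
#' @export
scoreEnrichment <- function(expr, geneSets, alpha = 0.25,
                            excludeFromAverage = "(?i)fibroblast") {
  .checkExprMatrix(expr)
  stopifnot(length(geneSets) > 0, !is.null(names(geneSets)))
  n <- nrow(expr)
  for (nm in names(geneSets)) {
    if (!any(geneSets[[nm]] %in% rownames(expr)))
      stop(sprintf("gene set '%s' shares no genes with the matrix", nm))
  }
  posWeight <- (n:1)^alpha  # weight by rank position, top first
  raw <- matrix(NA_real_, ncol(expr), length(geneSets),
                dimnames = list(colnames(expr), names(geneSets)))
  for (s in seq_len(ncol(expr))) {
    ord <- order(expr[, s], decreasing = TRUE)  # stable: row order on ties
    orderedGenes <- rownames(expr)[ord]
    for (j in seq_along(geneSets)) {
      inSet <- orderedGenes %in% geneSets[[j]]
      nIn <- sum(inSet)
      pin <- cumsum(posWeight * inSet) / sum(posWeight[inSet])
      pout <- if (nIn < n) cumsum(!inSet) / (n - nIn) else rep(0, n)
      raw[s, j] <- sum(pin - pout)
    }
  }
  scores <- apply(raw, 2, function(x) {
    rng <- range(x)
    if (diff(rng) == 0) x else (x - rng[1]) / diff(rng)
  })
  scores <- matrix(scores, nrow = nrow(raw), dimnames = dimnames(raw))
  keep <- !grepl(excludeFromAverage, colnames(scores), perl = TRUE)
  average <- if (any(keep)) rowMeans(scores[, keep, drop = FALSE]) else
    rep(NA_real_, nrow(scores))
  list(scores = scores, average = average)
}

#' Linear weighted score on the FPKM scale (DDIR scheme)
#'
#' `score = sum(weight_g * expr[g, ]) + bias` over the present weighted
#' genes, on the raw (linear) expression scale.
#'
#' @param expr raw FPKM-scale gene-by-sample matrix.
#' @param sig a [Signature-class] with scheme `linear_weighted`.
#' @return named numeric vector of scores.
#' @export
scoreLinearWeighted <- function(expr, sig) {
  keep <- sig@genes %in% rownames(expr)
  g <- .presentGenes(sig@genes, expr, sig@name)
  w <- sig@weights[keep]
  drop(crossprod(expr[g, , drop = FALSE], w))[colnames(expr)] + sig@bias
}

#' Score every signature of a registry on an expression matrix
#'
#' Dispatches each [Signature-class] of the registry to its scheme-specific
#' scorer. Continuous scores fill numeric columns; nearest-centroid
#' signatures contribute a character call column. Centroid correlations and
#' a per-signature missing-gene report are attached as attributes
#' (`"correlations"`, `"missing_genes"`).
#'
#' Mean/median centring makes the continuous scores a function of the whole
#' sample set: adding or removing samples changes all scores of the centred
#' schemes.
#'
#' @param expr raw FPKM-scale gene-by-sample matrix, or a
#'   `SummarizedExperiment` whose first assay is such a matrix.
#' @param registry a [SignatureSet-class].
#' @param pseudocount pseudocount for the internal log2 transform.
#' @param enrichmentAlpha rank-weight exponent for enrichment signatures.
#' @return data.frame with one row per sample (rownames = sample ids).
#' @export
setGeneric("scoreSignatures",
  function(expr, registry, pseudocount = 1, enrichmentAlpha = 0.25)
    standardGeneric("scoreSignatures"))

#' @rdname scoreSignatures
#' @export
setMethod("scoreSignatures", "matrix",
  function(expr, registry, pseudocount = 1, enrichmentAlpha = 0.25) {
  stopifnot(is(registry, "SignatureSet"))
  if (length(registry) == 0L) stop("empty signature registry")
  .checkExprMatrix(expr)
  exprLog2 <- log2Transform(expr, pseudocount)
  out <- data.frame(row.names = colnames(expr))
  correlations <- list()
  missingReport <- list()
  for (sig in as.list(registry)) {
    missingReport[[sig@name]] <- setdiff(sig@genes, rownames(expr))
    res <- withCallingHandlers(
      switch(sig@scheme,
        mean_centered = scoreMeanCentered(exprLog2, sig),
        weighted_normalized = scoreWeightedNormalized(expr, sig, pseudocount),
        nearest_centroid = classifyNearestCentroid(exprLog2, sig),
        negated_sum = scoreNegatedSum(exprLog2, sig),
        median_log2 = scoreMedianLog2(exprLog2, sig),
        single_gene = scoreSingleGene(exprLog2, sig@genes),
        first_pc = scoreFirstPC(exprLog2, sig),
        enrichment = scoreEnrichment(
          expr, setNames(list(sig@genes), sig@name),
          alpha = enrichmentAlpha)$scores[, 1],
        linear_weighted = scoreLinearWeighted(expr, sig),
        stop(sprintf("unknown scheme '%s'", sig@scheme))),
      error = function(e) {
        stop(sprintf("scoring signature '%s' failed: %s", sig@name,
                     conditionMessage(e)), call. = FALSE)
      })
    if (sig@scheme == "nearest_centroid") {
      out[[sig@name]] <- unname(res$calls[rownames(out)])
      correlations[[sig@name]] <- res$correlations
    } else {
      out[[sig@name]] <- unname(res[rownames(out)])
    }
  }
  attr(out, "correlations") <- correlations
  attr(out, "missing_genes") <- missingReport
  out
})

#' @rdname scoreSignatures
#' @export
setMethod("scoreSignatures", "SummarizedExperiment",
  function(expr, registry, pseudocount = 1, enrichmentAlpha = 0.25) {
    scoreSignatures(SummarizedExperiment::assay(expr), registry,
                    pseudocount = pseudocount,
                    enrichmentAlpha = enrichmentAlpha)
  })

#' Z-score the continuous columns of a score table
#'
#' Each numeric column is standardised to mean 0 and sample SD 1 over its
#' non-missing values; character/factor call columns pass through untouched.
#' Z-scoring is computed once on the full analysis cohort so per-arm models
#' share a scale.
#'
#' @param scores data.frame of scores (as from [scoreSignatures]).
#' @return data.frame of the same shape.
#' @export
zscoreColumns <- function(scores) {
  stopifnot(is.data.frame(scores))
  for (nm in names(scores)) {
    x <- scores[[nm]]
    if (!is.numeric(x)) next
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0)
      stop(sprintf("column '%s' has zero variance; cannot Z-score", nm))
    scores[[nm]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  scores
}
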
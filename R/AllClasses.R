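#' @import methods
#' @importFrom stats median cor sd quantile qlogis plogis rbinom rnorm runif
#'   rexp pnorm pchisq pt qt qnorm glm binomial coef vcov lm hclust cutree
#'   as.dist kruskal.test fisher.test t.test complete.cases setNames
#'   model.matrix fitted residuals p.adjust aggregate dist uniroot
#' @importFrom utils head read.delim write.csv read.csv combn
#' @useDynLib sigForest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom S4Vectors SimpleList DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

VALID_SCHEMES <- c("mean_centered", "weighted_normalized", "nearest_centroid",
                   "negated_sum", "median_log2", "single_gene", "first_pc",
                   "enrichment", "linear_weighted")

#' Signature: one transcriptional signature definition
#'
#' Declarative record of a single signature: which genes it uses and under
#' which scheme they are combined into a per-sample score. Slots not used by
#' a scheme stay empty. The `inputScale` slot records whether the scheme
#' consumes raw FPKM-scale values (`"linear"`, e.g. DDIR-style linear
#' weighted scores) or log2-transformed values (`"log2"`, most schemes).
#'
#' @slot name signature name.
#' @slot scheme one of `mean_centered`, `weighted_normalized`,
#'   `nearest_centroid`, `negated_sum`, `median_log2`, `single_gene`,
#'   `first_pc`, `enrichment`, `linear_weighted`.
#' @slot genes character vector of gene identifiers.
#' @slot weights per-gene weights (`weighted_normalized`, `linear_weighted`).
#' @slot bias scalar offset added to linear scores.
#' @slot normGenes normalization genes whose geometric mean divides the
#'   signature genes (`weighted_normalized`).
#' @slot centroids gene-by-class matrix of centroid profiles
#'   (`nearest_centroid`), rownames = genes.
#' @slot boundaries length-2 numeric; per-gene centred values are clipped
#'   into this interval before weighting (`weighted_normalized`), or empty.
#' @slot threshold optional decision cut on the continuous score.
#' @slot inputScale `"log2"` or `"linear"`.
#' @export
setClass("Signature",
  representation(name = "character", scheme = "character",
                 genes = "character", weights = "numeric", bias = "numeric",
                 normGenes = "character", centroids = "matrix",
                 boundaries = "numeric", threshold = "numeric",
                 inputScale = "character"),
  prototype(weights = numeric(0), bias = 0, normGenes = character(0),
            centroids = matrix(numeric(0), 0, 0), boundaries = numeric(0),
            threshold = numeric(0), inputScale = "log2"))

setValidity("Signature", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@scheme) != 1L || !object@scheme %in% VALID_SCHEMES)
    msg <- c(msg, sprintf("'scheme' must be one of: %s",
                          paste(VALID_SCHEMES, collapse = ", ")))
  if (length(object@genes) == 0L && object@scheme != "nearest_centroid")
    msg <- c(msg, "'genes' must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "'genes' must be duplicate-free")
  if (length(object@scheme) == 1L) {
    if (object@scheme %in% c("weighted_normalized", "linear_weighted")) {
      if (length(object@weights) != length(object@genes))
        msg <- c(msg, "'weights' must align 1:1 with 'genes'")
    }
    if (object@scheme == "weighted_normalized" &&
        length(object@normGenes) == 0L)
      msg <- c(msg, "'normGenes' must be non-empty for weighted_normalized")
    if (object@scheme == "nearest_centroid") {
      if (nrow(object@centroids) < 1L || ncol(object@centroids) < 2L)
        msg <- c(msg, "'centroids' needs >=2 class profiles")
      if (is.null(rownames(object@centroids)))
        msg <- c(msg, "'centroids' must have gene rownames")
    }
    if (object@scheme == "single_gene" && length(object@genes) != 1L)
      msg <- c(msg, "single_gene scheme takes exactly one gene")
  }
  if (length(object@boundaries) %in% c(0L, 2L) == FALSE)
    msg <- c(msg, "'boundaries' must be empty or length 2")
  if (!object@inputScale %in% c("log2", "linear"))
    msg <- c(msg, "'inputScale' must be 'log2' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' Construct a Signature
#'
#' @param name signature name.
#' @param scheme scoring scheme tag (see [Signature-class]).
#' @param genes gene identifiers (for `nearest_centroid` defaults to the
#'   centroid rownames).
#' @param weights,bias,normGenes,centroids,boundaries,threshold,inputScale
#'   scheme-specific fields, see [Signature-class].
#' @return a [Signature-class] object.
#' @examples
#' Signature("CIN70ish", "mean_centered", genes = paste0("g", 1:5))
#' @export
Signature <- function(name, scheme, genes = character(0),
                      weights = numeric(0), bias = 0,
                      normGenes = character(0),
                      centroids = matrix(numeric(0), 0, 0),
                      boundaries = numeric(0), threshold = numeric(0),
                      inputScale = if (identical(scheme, "linear_weighted"))
                        "linear" else "log2") {
  if (identical(scheme, "nearest_centroid") && length(genes) == 0L &&
      !is.null(rownames(centroids)))
    genes <- rownames(centroids)
  new("Signature", name = name, scheme = scheme, genes = as.character(genes),
      weights = as.numeric(weights), bias = as.numeric(bias),
      normGenes = as.character(normGenes), centroids = centroids,
      boundaries = as.numeric(boundaries), threshold = as.numeric(threshold),
      inputScale = inputScale)
}

setMethod("show", "Signature", function(object) {
  cat(sprintf("Signature '%s' [%s], %d gene(s)", object@name, object@scheme,
              length(object@genes)))
  if (length(object@normGenes))
    cat(sprintf(", %d normalization gene(s)", length(object@normGenes)))
  if (ncol(object@centroids))
    cat(sprintf(", %d centroid(s)", ncol(object@centroids)))
  cat("\n")
})

#' SignatureSet: an ordered registry of signatures
#'
#' A [S4Vectors::SimpleList] of [Signature-class] objects with unique names;
#' the declared order is meaningful (nearest-centroid ties are broken by
#' registry order).
#'
#' @export
setClass("SignatureSet", contains = "SimpleList")

setValidity("SignatureSet", function(object) {
  if (length(object) == 0L) return(TRUE)
  ok <- vapply(object, is, logical(1), class2 = "Signature")
  if (!all(ok)) return("all elements must be Signature objects")
  nm <- vapply(object, function(s) s@name, character(1))
  if (anyDuplicated(nm)) return("signature names must be unique")
  TRUE
})

#' Construct a SignatureSet
#'
#' @param ... [Signature-class] objects (or a single list of them).
#' @return a [SignatureSet-class].
#' @examples
#' SignatureSet(Signature("a", "median_log2", genes = "g1"))
#' @export
SignatureSet <- function(...) {
  sigs <- list(...)
  if (length(sigs) == 1L && is.list(sigs[[1]]) && !is(sigs[[1]], "Signature"))
    sigs <- sigs[[1]]
  names(sigs) <- vapply(sigs, function(s) s@name, character(1))
  new("SignatureSet", S4Vectors::SimpleList(sigs))
}

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet of %d signature(s)\n", length(object)))
  if (length(object)) {
    sch <- vapply(object, function(s) s@scheme, character(1))
    tab <- table(sch)
    cat("  schemes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
})

#' ConsensusResult: consensus clustering output
#'
#' Holds per-k consensus matrices, the CDF-area curve used to select the
#' number of clusters, and the final partition.
#'
#' @slot kRange candidate numbers of clusters.
#' @slot consensus named list of symmetric sample-by-sample consensus
#'   matrices (entries in \[0,1\], unit diagonal), one per k.
#' @slot cdfArea per-k area under the consensus CDF.
#' @slot deltaArea per-k relative increase in CDF area (non-negative).
#' @slot selectedK selected number of clusters.
#' @slot labels integer cluster label per sample at `selectedK`, ids ordered
#'   by decreasing cluster size.
#' @slot perRepLabels optional matrix of per-repetition partitions (audit).
#' @slot seed integer seed the run used.
#' @export
setClass("ConsensusResult",
  representation(kRange = "integer", consensus = "list", cdfArea = "numeric",
                 deltaArea = "numeric", selectedK = "integer",
                 labels = "integer", perRepLabels = "matrix",
                 seed = "integer"))

setValidity("ConsensusResult", function(object) {
  msg <- character(0)
  for (k in names(object@consensus)) {
    M <- object@consensus[[k]]
    if (!isSymmetric(unname(M), tol = 1e-8))
      msg <- c(msg, sprintf("consensus matrix k=%s not symmetric", k))
    if (any(M < -1e-8 | M > 1 + 1e-8))
      msg <- c(msg, sprintf("consensus k=%s entries outside [0,1]", k))
    if (any(abs(diag(M) - 1) > 1e-8))
      msg <- c(msg, sprintf("consensus k=%s diagonal != 1", k))
  }
  if (length(object@labels) &&
      length(unique(object@labels)) != object@selectedK)
    msg <- c(msg, "labels must take exactly selectedK distinct values")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: k in {%s}, selected k = %d, %d sample(s)\n",
              paste(object@kRange, collapse = ","), object@selectedK,
              length(object@labels)))
  cat("  cluster sizes:",
      paste(sort(table(object@labels), decreasing = TRUE), collapse = "/"),
      "\n")
  cat("  delta CDF area:",
      paste(sprintf("k=%d:%.3f", object@kRange, object@deltaArea),
            collapse = "  "), "\n")
})

#' Accessors for ConsensusResult
#'
#' @param object a [ConsensusResult-class].
#' @return `clusterLabels`: named integer vector of labels;
#'   `selectedK`: the selected number of clusters;
#'   `consensusMatrix`: the consensus matrix at a given `k`;
#'   `cdfAreaCurve`: data.frame with k, area and delta area.
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ConsensusResult", function(object) object@labels)

#' @rdname clusterLabels
#' @export
setGeneric("selectedK", function(object) standardGeneric("selectedK"))
#' @rdname clusterLabels
#' @export
setMethod("selectedK", "ConsensusResult", function(object) object@selectedK)

#' @rdname clusterLabels
#' @param k which candidate k; defaults to the selected one.
#' @export
setGeneric("consensusMatrix", function(object, k) {
  standardGeneric("consensusMatrix")
})
#' @rdname clusterLabels
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(object, k) {
  if (missing(k)) k <- object@selectedK
  object@consensus[[as.character(k)]]
})

#' @rdname clusterLabels
#' @export
setGeneric("cdfAreaCurve", function(object) standardGeneric("cdfAreaCurve"))
#' @rdname clusterLabels
#' @export
setMethod("cdfAreaCurve", "ConsensusResult", function(object) {
  data.frame(k = object@kRange, cdf_area = object@cdfArea,
             delta_area = object@deltaArea)
})
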
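# File formats and end-to-end orchestration: expression TSV (genes in rows),
# clinical CSV, GMT gene sets, a YAML signature registry, and runPipeline()
# which chains scoring -> Z-scores -> per-arm associations -> feature
# selection -> consensus clustering -> cluster characterization, writing
# CSV artifacts plus a run manifest with md5 checksums.

.sfError <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column gene ids, header row of sample ids. Duplicate identifiers,
#' non-numeric cells and negative values are rejected with coordinates.
#'
#' @param path TSV file path.
#' @return validated numeric matrix.
#' @export
readExpressionTSV <- function(path) {
  if (!file.exists(path)) .sfError("sfIOError", "file not found: %s", path)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(raw[[1]])
  dup <- which(duplicated(genes))
  if (length(dup))
    .sfError("sfIOError", "duplicated gene id '%s' at data row %d in %s",
             genes[dup[1]], dup[1], path)
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(x) & !is.na(vals[[j]]))
    if (length(bad))
      .sfError("sfIOError",
               "non-numeric cell at gene '%s', sample '%s' in %s",
               genes[bad[1]], names(vals)[j], path)
    vals[[j]] <- x
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(colnames(m)))
    .sfError("sfIOError", "duplicated sample ids in %s", path)
  if (any(is.na(m)))
    .sfError("sfIOError", "missing values in expression matrix %s", path)
  if (any(m < 0))
    .sfError("sfIOError", "negative expression values in %s", path)
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr gene-by-sample matrix.
#' @param path output path.
#' @export
writeExpressionTSV <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then gene ids.
#' Within-set duplicate genes are dropped with a warning; duplicate set
#' names and lines with fewer than 3 fields are errors.
#'
#' @param path GMT file path.
#' @return named list of gene id vectors (ordered as in the file).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) .sfError("sfIOError", "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning(sprintf("empty GMT file: %s", path), call. = FALSE)
    return(list())
  }
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      .sfError("sfIOError", "GMT line %d has fewer than 3 fields in %s",
               i, path)
    nm <- fields[1]
    if (nm %in% names(out))
      .sfError("sfIOError", "duplicate gene set name '%s' in %s", nm, path)
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("set '%s': duplicate genes de-duplicated", nm),
              call. = FALSE)
      genes <- unique(genes)
    }
    out[[nm]] <- genes
  }
  out
}

#' Write gene sets as GMT
#' @param sets named list of gene vectors.
#' @param path output path.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

.clinicalEnums <- list(
  arm = c("carboplatin", "docetaxel"),
  brca_status = c("BRCA1_mutated", "BRCA2_mutated", "BRCA1_methylated",
                  "wildtype", "uncertain"),
  timepoint = c("primary", "recurrence"))

#' Read and validate a clinical table from CSV
#'
#' Required columns: sample_id, patient_id, arm, response, pfs_time,
#' pfs_event, tils, brca_status, prior_chemo, timepoint. Enumerated columns
#' are validated against their allowed values and `pfs_time > 0` is
#' enforced.
#'
#' @param path CSV file path.
#' @return data.frame keyed by sample_id.
#' @export
readClinicalCSV <- function(path) {
  if (!file.exists(path)) .sfError("sfIOError", "file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "patient_id", "arm", "response", "pfs_time",
                "pfs_event", "tils", "brca_status", "prior_chemo",
                "timepoint")
  missing <- setdiff(required, names(df))
  if (length(missing))
    .sfError("sfIOError", "clinical table missing column(s): %s",
             paste(missing, collapse = ", "))
  for (col in names(.clinicalEnums)) {
    bad <- setdiff(unique(df[[col]]), .clinicalEnums[[col]])
    if (length(bad))
      .sfError("sfIOError",
               "unknown %s value(s) %s; allowed: %s", col,
               paste(sQuote(bad), collapse = ", "),
               paste(.clinicalEnums[[col]], collapse = ", "))
  }
  badT <- which(!(df$pfs_time > 0))
  if (length(badT))
    .sfError("sfIOError", "pfs_time must be > 0 (row %d)", badT[1])
  if (anyDuplicated(df$sample_id))
    .sfError("sfIOError", "duplicated sample_id in %s", path)
  rownames(df) <- df$sample_id
  df
}

#' Write / read a signature registry as YAML
#'
#' One document with a list of signature entries keyed by scheme, carrying
#' genes, weights, bias, normalization genes, centroid profiles, boundaries
#' and input scale, so weighted and centroid signature content lives
#' outside code.
#'
#' @param registry a [SignatureSet-class].
#' @param path YAML file path.
#' @return `writeSignatureRegistry` returns the path invisibly;
#'   `readSignatureRegistry` returns a [SignatureSet-class].
#' @export
writeSignatureRegistry <- function(registry, path) {
  entries <- lapply(as.list(registry), function(s) {
    e <- list(name = s@name, scheme = s@scheme, genes = as.list(s@genes),
              input_scale = s@inputScale)
    if (length(s@weights)) e$weights <- as.list(s@weights)
    if (length(s@bias) && s@bias != 0) e$bias <- s@bias
    if (length(s@normGenes)) e$normalization_genes <- as.list(s@normGenes)
    if (ncol(s@centroids)) {
      e$centroid_genes <- as.list(rownames(s@centroids))
      e$centroids <- lapply(seq_len(ncol(s@centroids)), function(j)
        list(label = colnames(s@centroids)[j],
             profile = as.list(unname(s@centroids[, j]))))
    }
    if (length(s@boundaries)) e$boundaries <- as.list(s@boundaries)
    if (length(s@threshold)) e$threshold <- s@threshold
    e
  })
  yaml::write_yaml(list(signatures = unname(entries)), path)
  invisible(path)
}

#' @rdname writeSignatureRegistry
#' @export
readSignatureRegistry <- function(path) {
  if (!file.exists(path)) .sfError("sfIOError", "file not found: %s", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$signatures))
    .sfError("sfIOError", "registry %s has no 'signatures' key", path)
  sigs <- lapply(doc$signatures, function(e) {
    centroids <- matrix(numeric(0), 0, 0)
    if (!is.null(e$centroids)) {
      centroids <- vapply(e$centroids, function(cc)
        unlist(cc$profile), numeric(length(e$centroid_genes)))
      colnames(centroids) <- vapply(e$centroids, `[[`, character(1), "label")
      rownames(centroids) <- unlist(e$centroid_genes)
    }
    Signature(name = e$name, scheme = e$scheme,
              genes = as.character(unlist(e$genes)),
              weights = as.numeric(unlist(e$weights)),
              bias = if (is.null(e$bias)) 0 else e$bias,
              normGenes = as.character(unlist(e$normalization_genes)),
              centroids = centroids,
              boundaries = as.numeric(unlist(e$boundaries)),
              threshold = as.numeric(unlist(e$threshold)),
              inputScale = if (is.null(e$input_scale))
                if (identical(e$scheme, "linear_weighted")) "linear"
                else "log2" else e$input_scale)
  })
  SignatureSet(sigs)
}

#' Pipeline configuration
#'
#' @param expression,clinical,registry input file paths (TSV / CSV / YAML).
#' @param modulesGmt optional GMT of characterization modules; when absent,
#'   the continuous signature scores double as module scores.
#' @param outDir output directory (created if needed).
#' @param pseudocount,enrichmentAlpha scoring options.
#' @param kRange,nReps,featureFrac,nTrees,clusterAlpha,deltaAreaThreshold
#'   clustering options.
#' @param tau,alpha,adjustment association options (`alpha` is both the
#'   significance level and the feature-selection rule's cut).
#' @param minSubgroupN smallest subgroup size on which per-subgroup models
#'   are attempted (chemotherapy-naive analyses are skipped below it).
#' @param seed root seed; all stage seeds derive from it (no wall-clock
#'   default).
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(expression, clinical, registry,
                           modulesGmt = NULL, outDir = "sigforest_out",
                           pseudocount = 1, enrichmentAlpha = 0.25,
                           kRange = 2:6, nReps = 100L, featureFrac = 0.8,
                           nTrees = 100L, clusterAlpha = 0.05,
                           deltaAreaThreshold = 0.05, tau = NULL,
                           alpha = 0.05, adjustment = "none",
                           minSubgroupN = 15L, seed) {
  if (missing(seed))
    .sfError("sfConfigError", "seed must be set explicitly")
  structure(list(expression = expression, clinical = clinical,
                 registry = registry, modulesGmt = modulesGmt,
                 outDir = outDir, pseudocount = pseudocount,
                 enrichmentAlpha = enrichmentAlpha, kRange = kRange,
                 nReps = nReps, featureFrac = featureFrac, nTrees = nTrees,
                 clusterAlpha = clusterAlpha,
                 deltaAreaThreshold = deltaAreaThreshold, tau = tau,
                 alpha = alpha, adjustment = adjustment,
                 minSubgroupN = minSubgroupN, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Univariable association scan over all continuous biomarkers
#'
#' For every continuous score column: per-arm logistic ORR models, per-arm
#' RMST regressions, and the treatment interaction tests, in the overall
#' cohort and the prior-chemotherapy / chemotherapy-naive subgroups (the
#' latter skipped with a warning below `minSubgroupN` samples or when
#' degenerate).
#'
#' @param zscores data.frame of Z-scored scores (rownames = sample ids).
#' @param clinical clinical data.frame aligned to the same samples.
#' @param tau RMST horizon (NULL = automatic per analysis set).
#' @param minSubgroupN minimum subgroup size.
#' @return tidy data.frame of association rows.
#' @export
associationScan <- function(zscores, clinical, tau = NULL,
                            minSubgroupN = 15L) {
  stopifnot(all(rownames(zscores) == clinical$sample_id))
  numCols <- names(zscores)[vapply(zscores, is.numeric, logical(1))]
  subgroups <- list(all = rep(TRUE, nrow(clinical)),
                    prior_chemo = clinical$prior_chemo == 1,
                    chemo_naive = clinical$prior_chemo == 0)
  rows <- list()
  for (sg in names(subgroups)) {
    idx <- subgroups[[sg]]
    if (sum(idx) < minSubgroupN) {
      warning(sprintf("subgroup '%s' below %d samples; skipped", sg,
                      minSubgroupN), call. = FALSE)
      next
    }
    for (bm in numCols) {
      z <- zscores[[bm]]
      for (a in unique(clinical$arm)) {
        sel <- idx & clinical$arm == a
        rows[[length(rows) + 1]] <- tryCatch(
          fitLogisticORR(z, clinical$response, subset = sel,
                         biomarker = bm, subgroup = sg, arm = a),
          error = function(e) .assocRow(bm, sg, a, NA, NA, NA, NA,
                                        sum(sel), note = "not_estimable"))
        rows[[length(rows) + 1]] <- tryCatch({
          r <- rmstRegression(clinical$pfs_time, clinical$pfs_event, z,
                              tau = tau, subset = sel, biomarker = bm,
                              subgroup = sg)
          r$arm <- a
          r$note <- paste0(r$note, ";pfs")
          r
        }, error = function(e) .assocRow(bm, sg, a, NA, NA, NA, NA,
                                         sum(sel), note = "not_estimable;pfs"))
      }
      rows[[length(rows) + 1]] <- tryCatch(
        testInteraction(z[idx], clinical$response[idx], clinical$arm[idx],
                        biomarker = bm, subgroup = sg),
        error = function(e) .assocRow(bm, sg, "interaction", NA, NA, NA, NA,
                                      sum(idx), note = "not_estimable"))
    }
  }
  do.call(rbind, rows)
}

#' Select the clustering feature table
#'
#' Continuous features are the biomarkers with any univariable association
#' p below `alpha` in any arm, subgroup or endpoint (ORR or PFS), Z-scored;
#' TILs are always included; BRCA status enters as a categorical feature.
#'
#' @param associations output of [associationScan].
#' @param zscores Z-scored score table.
#' @param clinical clinical data.frame.
#' @param alpha selection level (1 keeps everything; an empty selection is
#'   an error suggesting relaxation).
#' @return data.frame feature table (attribute `"selected"` lists the
#'   selected biomarkers).
#' @export
selectClusteringFeatures <- function(associations, zscores, clinical,
                                     alpha = 0.05) {
  hits <- unique(associations$biomarker[!is.na(associations$p) &
                                          associations$p < alpha])
  if (length(hits) == 0L)
    .sfError("sfStatsError",
             "no biomarker passes p < %g in any setting; relax alpha", alpha)
  ft <- zscores[, intersect(names(zscores), hits), drop = FALSE]
  tilsZ <- clinical$tils
  ft$TILs <- (tilsZ - mean(tilsZ, na.rm = TRUE)) / sd(tilsZ, na.rm = TRUE)
  ft$BRCA_status <- factor(clinical$brca_status)
  rownames(ft) <- clinical$sample_id
  attr(ft, "selected") <- hits
  ft
}

#' Characterize consensus clusters
#'
#' Orders characterization modules by average-linkage hierarchical
#' clustering of their score profiles, groups samples by cluster label
#' (supervised: samples are never reordered across cluster boundaries),
#' and tabulates per-cluster per-arm response rates.
#'
#' @param labels named cluster labels.
#' @param moduleScores data.frame/matrix of module scores (samples in
#'   rows).
#' @param clinical clinical data.frame aligned to the samples.
#' @return a `CharacterizationReport` list: `sizes`, `response`,
#'   `module_order`, `sample_order`, `cluster_means`, `flags`.
#' @export
characterizeClusters <- function(labels, moduleScores, clinical) {
  moduleScores <- as.data.frame(moduleScores)
  num <- moduleScores[vapply(moduleScores, is.numeric, logical(1))]
  stopifnot(nrow(num) == length(labels))
  m <- scale(as.matrix(num))
  m[!is.finite(m)] <- 0
  modOrder <- if (ncol(m) > 2) {
    colnames(m)[hclust(dist(t(m)), method = "average")$order]
  } else colnames(m)
  sampleOrder <- rownames(num)[order(labels)]
  sizes <- table(labels)
  clusterMeans <- aggregate(num, by = list(cluster = labels), FUN = mean)
  resp <- responseRateTable(labels, clinical$arm, clinical$response)
  structure(list(sizes = sizes, response = resp, module_order = modOrder,
                 sample_order = sampleOrder, cluster_means = clusterMeans,
                 flags = resp$flag[nzchar(resp$flag)]),
            class = "CharacterizationReport")
}

#' @export
print.CharacterizationReport <- function(x, ...) {
  cat("Cluster characterization\n  sizes:",
      paste(sprintf("%s:%d", names(x$sizes), x$sizes), collapse = "  "),
      "\n")
  print(x$response)
  invisible(x)
}

.writeStage <- function(df, outDir, name) {
  path <- file.path(outDir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline from files to report
#'
#' Executes scoring, Z-scoring, the univariable association scan,
#' clustering-feature selection, consensus forest clustering and cluster
#' characterization, writing every stage's output as CSV under
#' `config$outDir` together with a manifest of md5 checksums. Reruns with
#' the same config and seed are byte-identical.
#'
#' @param config a [pipelineConfig] object.
#' @return (invisibly) list with the in-memory stage results and the
#'   manifest path.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = unique(c(class(e), "error", "condition")),
                     list(message = sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)),
                          call = NULL)))
    })
  }
  expr <- stage("read_expression", readExpressionTSV(config$expression))
  clinical <- stage("read_clinical", readClinicalCSV(config$clinical))
  registry <- stage("read_registry", readSignatureRegistry(config$registry))
  shared <- intersect(colnames(expr), clinical$sample_id)
  dropped <- setdiff(union(colnames(expr), clinical$sample_id), shared)
  if (length(dropped))
    message(sprintf("join: %d sample(s) dropped (%s)", length(dropped),
                    paste(head(dropped, 5), collapse = ", ")))
  expr <- expr[, shared, drop = FALSE]
  clinical <- clinical[shared, , drop = FALSE]
  primary <- clinical$timepoint == "primary"

  scores <- stage("score", scoreSignatures(
    expr, registry, pseudocount = config$pseudocount,
    enrichmentAlpha = config$enrichmentAlpha))
  outFiles <- .writeStage(data.frame(sample_id = rownames(scores), scores),
                          config$outDir, "scores.csv")
  scoresP <- scores[primary, , drop = FALSE]
  clinP <- clinical[primary, , drop = FALSE]
  zsc <- stage("zscore", zscoreColumns(scoresP))

  assoc <- stage("associate", associationScan(
    zsc, clinP, tau = config$tau, minSubgroupN = config$minSubgroupN))
  outFiles <- c(outFiles, .writeStage(assoc, config$outDir,
                                      "associations.csv"))

  feats <- stage("select_features", selectClusteringFeatures(
    assoc, zsc, clinP, alpha = config$alpha))
  outFiles <- c(outFiles, .writeStage(
    data.frame(biomarker = attr(feats, "selected")), config$outDir,
    "selected_features.csv"))

  cc <- stage("cluster", consensusCluster(
    feats, kRange = config$kRange, nReps = config$nReps,
    featureFrac = config$featureFrac, nTrees = config$nTrees,
    alpha = config$clusterAlpha,
    deltaAreaThreshold = config$deltaAreaThreshold, seed = config$seed))
  outFiles <- c(outFiles,
    .writeStage(data.frame(sample_id = names(clusterLabels(cc)),
                           cluster = clusterLabels(cc)),
                config$outDir, "cluster_labels.csv"),
    .writeStage(cdfAreaCurve(cc), config$outDir, "cdf_area.csv"),
    .writeStage(as.data.frame(consensusMatrix(cc)), config$outDir,
                "consensus_matrix.csv"))

  moduleScores <- if (!is.null(config$modulesGmt)) {
    sets <- stage("read_modules", readGMT(config$modulesGmt))
    lg <- log2Transform(expr[, primary, drop = FALSE], config$pseudocount)
    as.data.frame(lapply(sets, function(g)
      scoreMedianLog2(lg, Signature("m", "median_log2", genes = g))),
      row.names = rownames(scoresP))
  } else {
    scoresP[vapply(scoresP, is.numeric, logical(1))]
  }
  report <- stage("characterize", characterizeClusters(
    clusterLabels(cc), moduleScores, clinP))
  outFiles <- c(outFiles,
    .writeStage(report$response, config$outDir, "cluster_response.csv"),
    .writeStage(report$cluster_means, config$outDir, "cluster_means.csv"))

  manifest <- data.frame(file = basename(outFiles),
                         md5 = unname(tools::md5sum(outFiles)))
  manifestPath <- file.path(config$outDir, "manifest.csv")
  write.csv(manifest, manifestPath, row.names = FALSE)
  invisible(list(scores = scores, zscores = zsc, associations = assoc,
                 features = feats, clustering = cc, report = report,
                 manifest = manifestPath))
}

#' Write the synthetic cohort to pipeline input files
#'
#' @param cohort a cohort from [generateCohort] (optionally extended with
#'   recurrences).
#' @param registry the matching [SignatureSet-class].
#' @param dir output directory.
#' @return named list of written paths.
#' @export
writeCohortFiles <- function(cohort, registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                clinical = file.path(dir, "clinical.csv"),
                registry = file.path(dir, "registry.yaml"),
                truth = file.path(dir, "truth.csv"))
  writeExpressionTSV(SummarizedExperiment::assay(cohort), paths$expression)
  clin <- clinicalTable(cohort)
  write.csv(clin[setdiff(names(clin), "true_cluster")], paths$clinical,
            row.names = FALSE)
  writeSignatureRegistry(registry, paths$registry)
  truth <- S4Vectors::metadata(cohort)$truth
  write.csv(data.frame(sample_id = colnames(cohort),
                       true_cluster = clinicalTable(cohort)$true_cluster),
            paths$truth, row.names = FALSE)
  paths
}
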
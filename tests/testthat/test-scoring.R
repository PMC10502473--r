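test_that("log2 transform matches direct recomputation and guards zeros", {
  m <- matrix(c(0, 7, 3, 1), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lt <- log2Transform(m, 1)
  expect_equal(lt["g1", "s1"], 0)
  expect_equal(lt["g2", "s1"], 3)
  fp <- randomFpkm(5, 4, seed = 42)
  expect_equal(log2Transform(fp, 1), log2(fp + 1), tolerance = 1e-12)
  expect_error(log2Transform(m, 0), "log2\\(0\\)")
  expect_error(log2Transform(m - 1, 1), ">= 0")
})

test_that("mean-centred scores centre to zero and match hand arithmetic", {
  lg <- matrix(c(1, 3, 3, 3), 2, 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sig <- Signature("cin", "mean_centered", genes = c("g1", "g2"))
  sc <- scoreMeanCentered(lg, sig)
  expect_equal(unname(sc), c(-0.5, 0.5))
  fp <- log2Transform(randomFpkm(8, 6, seed = 2))
  sig2 <- Signature("x", "mean_centered", genes = rownames(fp)[1:5])
  sc2 <- scoreMeanCentered(fp, sig2)
  expect_lt(abs(sum(sc2)), 1e-9)
  # permuting samples permutes scores identically
  perm <- c(3, 1, 2, 6, 5, 4)
  expect_equal(scoreMeanCentered(fp[, perm], sig2), sc2[perm])
  suppressWarnings(  # the missing-gene log precedes the error by design
    expect_error(scoreMeanCentered(fp, Signature("y", "mean_centered",
                                                 genes = "nope")), "y"))
})

test_that("weighted-normalised scoring reduces to bias and matches oracle", {
  fp <- randomFpkm(10, 6, seed = 3)
  g <- rownames(fp)
  # identical values for all genes within each sample -> ratios 1 -> 0
  same <- matrix(rep(c(2, 5, 9, 1, 3, 7), each = 4), 4, 6, byrow = FALSE,
                 dimnames = list(g[1:4], colnames(fp)))
  sigSame <- Signature("p7", "weighted_normalized", genes = g[1:4],
                       weights = rep(1, 4), normGenes = g[1:4])
  expect_equal(unname(scoreWeightedNormalized(same, sigSame)), rep(0, 6))
  sig0 <- Signature("p0", "weighted_normalized", genes = g[1:4],
                    weights = rep(0, 4), bias = 2.5, normGenes = g[5:8])
  expect_equal(unname(scoreWeightedNormalized(fp, sig0)), rep(2.5, 6))
  w <- c(0.7, -0.2, 0.4, 1.1)
  sig <- Signature("pw", "weighted_normalized", genes = g[1:4], weights = w,
                   normGenes = g[5:8], boundaries = c(-1, 1), bias = 0.3)
  expect_scores_equal(scoreWeightedNormalized(fp, sig),
                      oracleWeightedNormalized(fp, g[1:4], w, g[5:8],
                                               c(-1, 1), 0.3), tol = 1e-9)
  expect_error(scoreWeightedNormalized(fp, Signature(
    "pm", "weighted_normalized", genes = g[1:2], weights = c(1, 1),
    normGenes = c(g[5], "absent"))), "absent")
})

test_that("nearest-centroid assignment is rank-based with audit trail", {
  genes <- paste0("g", 1:5)
  centroids <- cbind(A = c(1, 2, 3, 5, 4), B = c(5, 4, 3, 2, 1))
  rownames(centroids) <- genes
  sig <- Signature("tp53", "nearest_centroid", centroids = centroids)
  lg <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(genes, "s1"))
  res <- classifyNearestCentroid(lg, sig)
  expect_equal(unname(res$calls), "A")
  expect_equal(unname(res$correlations[1, ]), c(0.9, -1))
  # strictly decreasing transform of centroid A still classifies as A
  lgA <- matrix(-exp(-centroids[, "A"]), 5, 1,
                dimnames = list(genes, "s1"))
  expect_equal(unname(classifyNearestCentroid(lgA, sig)$calls), "A")
  lgExact <- matrix(centroids[, "B"], 5, 1, dimnames = list(genes, "s1"))
  resB <- classifyNearestCentroid(lgExact, sig)
  expect_equal(unname(resB$calls), "B")
  expect_equal(unname(resB$correlations[1, "B"]), 1)
  # constant profile is unclassifiable; <3 shared genes errors
  lgConst <- matrix(2, 5, 1, dimnames = list(genes, "s1"))
  expect_warning(resC <- classifyNearestCentroid(lgConst, sig),
                 "unclassifiable")
  expect_equal(unname(resC$calls), "unclassifiable")
  lgTwo <- lg[1:2, , drop = FALSE]
  expect_error(classifyNearestCentroid(lgTwo, sig), ">=3")
})

test_that("negated-sum scores are median-anchored and match oracle", {
  lg <- log2Transform(randomFpkm(6, 7, seed = 4))
  g <- rownames(lg)[1:4]
  sig <- Signature("rps", "negated_sum", genes = g)
  # a sample sitting at every gene's median scores 0
  lg2 <- lg
  lg2[g, 4] <- apply(lg[g, ], 1, median)
  med <- apply(lg2[g, ], 1, median)
  if (all(med == lg2[g, 4])) {
    expect_equal(unname(scoreNegatedSum(lg2, sig)[4]), 0)
  }
  # one gene one unit above its median, others at median -> -1
  lg3 <- matrix(rep(c(0, 0, 0), each = 4), 4, 3,
                dimnames = list(g, c("a", "b", "c")))
  lg3[, 3] <- c(1, 0, 0, 0) + lg3[, 3]
  expect_equal(unname(scoreNegatedSum(lg3, sig)["c"]), -1)
  expect_scores_equal(scoreNegatedSum(lg, sig), oracleNegatedSum(lg, g),
                      tol = 1e-12)
})

test_that("median and single-gene scores follow their definitions", {
  lg <- matrix(c(1, 5, 100), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  sig <- Signature("m", "median_log2", genes = rownames(lg))
  expect_equal(unname(scoreMedianLog2(lg, sig)), 5)
  one <- Signature("o", "median_log2", genes = "g2")
  expect_equal(unname(scoreMedianLog2(lg, one)), 5)
  fp <- randomFpkm(9, 5, seed = 5)
  lgr <- log2Transform(fp)
  g <- rownames(lgr)[c(2, 5, 7, 8)]
  expect_scores_equal(scoreMedianLog2(lgr, Signature("r", "median_log2",
                                                     genes = g)),
                      oracleMedianLog2(lgr, g), tol = 1e-12)
  expect_equal(scoreSingleGene(lgr, "g03"), lgr["g03", ])
  expect_error(scoreSingleGene(lgr, "absent"), "absent")
})

test_that("top differential genes are filtered strictly and capped", {
  de <- data.frame(gene_id = sprintf("d%03d", 1:60),
                   log_fold_change = rep(2, 60), fdr = rep(0.001, 60),
                   cell_type = "CD8_TRM")
  expect_length(selectTopGenes(de, "CD8_TRM"), 50)
  deB <- rbind(de, data.frame(gene_id = "edge", log_fold_change = 1,
                              fdr = 1e-9, cell_type = "CD8_TRM"))
  expect_false("edge" %in% selectTopGenes(deB, "CD8_TRM"))
  set.seed(6)
  deR <- data.frame(gene_id = sprintf("r%03d", 1:200),
                    log_fold_change = round(rnorm(200, 1, 0.7), 1),
                    fdr = round(runif(200, 0, 0.05), 3),
                    cell_type = sample(c("a", "b"), 200, TRUE))
  got <- selectTopGenes(deR, "a", nTop = 20)
  sub <- deR[deR$cell_type == "a" & deR$log_fold_change > 1 &
               deR$fdr < 0.01, ]
  sub <- sub[order(-sub$log_fold_change, sub$fdr, sub$gene_id), ]
  expect_identical(got, head(sub$gene_id, 20))
  expect_warning(none <- selectTopGenes(deR, "a", lfcMin = 99), "filter")
  expect_length(none, 0)
})

test_that("first-PC scores recover rank-1 structure and match eigen oracle", {
  genes <- paste0("g", 1:4)
  pattern <- c(2, -1, 0.5, 3, -2, 1)
  loading <- c(1, 0.8, -0.5, 0.3)
  lg <- outer(loading, pattern) + 5
  dimnames(lg) <- list(genes, paste0("s", 1:6))
  sig <- Signature("pc", "first_pc", genes = genes)
  sc <- scoreFirstPC(lg, sig)
  expect_gt(abs(cor(sc, pattern)), 1 - 1e-9)
  lgr <- log2Transform(randomFpkm(8, 7, seed = 7))
  sigr <- Signature("pcr", "first_pc", genes = rownames(lgr)[1:6])
  got <- scoreFirstPC(lgr, sigr)
  want <- oracleFirstPC(lgr, rownames(lgr)[1:6])
  expect_lt(min(max(abs(got - want)), max(abs(got + want))), 1e-8)
  # orientation contract over many draws
  for (s in 1:10) {
    lgi <- log2Transform(randomFpkm(6, 9, seed = 100 + s))
    sigi <- Signature("p", "first_pc", genes = rownames(lgi)[1:5])
    sci <- scoreFirstPC(lgi, sigi)
    expect_gte(cor(sci, colMeans(lgi[rownames(lgi)[1:5], ])), 0)
  }
  flat <- matrix(3, 4, 5, dimnames = list(genes, paste0("s", 1:5)))
  expect_error(scoreFirstPC(flat, sig), "zero-variance")
})

test_that("rank enrichment matches brute-force running sum and is monotone", {
  fp <- randomFpkm(20, 4, seed = 8)
  genes <- rownames(fp)[c(3, 7, 11, 15, 19)]
  got <- scoreEnrichment(fp, list(set = genes))$scores[, "set"]
  expect_scores_equal(got, oracleEnrichment(fp, genes), tol = 1e-9)
  # degenerate set covering every gene cannot discriminate samples
  all <- scoreEnrichment(fp, list(everything = rownames(fp)))
  expect_lt(diff(range(all$scores[, 1])), 1e-12)
  # top-ranked set genes beat bottom-ranked set genes
  n <- 20
  top <- matrix(c(seq(n, 1), seq(1, n)), n, 2,
                dimnames = list(sprintf("g%02d", 1:n), c("hi", "lo")))
  sc <- scoreEnrichment(top, list(s = sprintf("g%02d", 1:5)))$scores
  expect_gt(sc["hi", "s"], sc["lo", "s"])
  expect_error(scoreEnrichment(fp, list(bad = "absent")), "bad")
  # fibroblast sets stay out of the average score
  two <- scoreEnrichment(fp, list(T_cells = genes,
                                  Fibroblasts = rownames(fp)[1:5]))
  expect_equal(two$average, two$scores[, "T_cells"])
})

test_that("linear weighted scores are affine in expression", {
  fp <- randomFpkm(5, 4, seed = 9)
  g <- rownames(fp)[1:3]
  sig0 <- Signature("d0", "linear_weighted", genes = g,
                    weights = rep(0, 3), bias = 1.25)
  expect_equal(unname(scoreLinearWeighted(fp, sig0)), rep(1.25, 4))
  hand <- matrix(c(2, 3, 1), 3, 1, dimnames = list(g, "s"))
  sigH <- Signature("dh", "linear_weighted", genes = g,
                    weights = c(1, -1, 2), bias = 0.5)
  expect_equal(unname(scoreLinearWeighted(hand, sigH)), 1.5)
  sig <- Signature("dd", "linear_weighted", genes = g,
                   weights = c(0.2, -0.4, 1), bias = 0.7)
  s1 <- scoreLinearWeighted(fp, sig)
  s3 <- scoreLinearWeighted(3 * fp, sig)
  expect_equal(s3, 3 * (s1 - 0.7) + 0.7, tolerance = 1e-9)
  expect_scores_equal(s1, oracleLinearWeighted(fp, g, c(0.2, -0.4, 1), 0.7),
                      tol = 1e-12)
})

test_that("scoreSignatures dispatches every scheme consistently", {
  fp <- randomFpkm(10, 8, seed = 10)
  reg <- tinyRegistry(fp)
  tab <- scoreSignatures(fp, reg)
  expect_equal(nrow(tab), 8)
  expect_setequal(names(tab), names(reg))
  num <- tab[vapply(tab, is.numeric, logical(1))]
  expect_true(all(vapply(num, function(x) all(is.finite(x)), logical(1))))
  lg <- log2Transform(fp)
  expect_equal(tab$mc, unname(scoreMeanCentered(lg, reg[["mc"]])))
  expect_equal(tab$ns, unname(scoreNegatedSum(lg, reg[["ns"]])))
  expect_equal(tab$lw, unname(scoreLinearWeighted(fp, reg[["lw"]])))
  expect_equal(tab$nc, unname(classifyNearestCentroid(lg, reg[["nc"]])$calls))
  expect_error(scoreSignatures(fp, SignatureSet(list())), "empty")
  # identical via the SummarizedExperiment method
  se <- SummarizedExperiment::SummarizedExperiment(list(fpkm = fp))
  expect_equal(scoreSignatures(se, reg), tab)
})

test_that("scores are cohort-dependent under centring schemes", {
  fp <- randomFpkm(10, 8, seed = 11)
  reg <- tinyRegistry(fp)
  full <- scoreSignatures(fp, reg)
  sub <- scoreSignatures(fp[, 1:7], reg)
  expect_false(isTRUE(all.equal(full$mc[1:7], sub$mc)))
  # single-gene scores do not depend on the cohort
  expect_equal(full$sg[1:7], sub$sg)
})

test_that("Z-scoring standardises numeric columns only", {
  df <- data.frame(a = c(1, 2, 3), b = c(10, 10, 40),
                   call = c("x", "y", "x"))
  z <- zscoreColumns(df)
  expect_equal(z$a, c(-1, 0, 1))
  expect_identical(z$call, df$call)
  for (cl in c("a", "b")) {
    expect_lt(abs(mean(z[[cl]])), 1e-9)
    expect_equal(sd(z[[cl]]), 1, tolerance = 1e-9)
  }
  expect_equal(zscoreColumns(data.frame(a = 2 * df$a + 5))$a, z$a)
  expect_error(zscoreColumns(data.frame(k = rep(1, 3))), "k")
})
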
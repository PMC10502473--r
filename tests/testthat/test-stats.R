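test_that("logistic ORR matches the 2x2 cross-product ratio", {
  # cells (a,b,c,d) = (8,2,2,8): responders/non by high/low biomarker
  z <- rep(c(1, 0), c(10, 10))
  resp <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  res <- fitLogisticORR(z, resp, biomarker = "bin")
  expect_equal(exp(res$estimate), 16, tolerance = 1e-4)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(res$n, 20)
})

test_that("separation is flagged instead of reported", {
  z <- c(rnorm(10, -3), rnorm(10, 3))
  resp <- rep(c(0, 1), each = 10)
  res <- fitLogisticORR(z, resp)
  expect_equal(res$note, "separation")
  expect_true(is.na(res$estimate))
  expect_error(fitLogisticORR(rnorm(10), rep(1, 10)), "responders")
})

test_that("interaction coefficient flips sign under arm relabeling", {
  set.seed(41)
  n <- 200
  arm <- rep(c("carboplatin", "docetaxel"), n / 2)
  z <- rnorm(n)
  eta <- -0.5 + ifelse(arm == "docetaxel", 1, -1) * z
  resp <- rbinom(n, 1, plogis(eta))
  r1 <- testInteraction(z, resp, arm)
  r2 <- testInteraction(z, resp, factor(arm, levels = c("docetaxel",
                                                        "carboplatin")))
  expect_equal(r1$estimate, -r2$estimate, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
  expect_lt(r1$p, 0.01)  # strong opposite-sign effect is detected
  expect_error(testInteraction(z, resp, rep("a", n)), "arms")
  # Wald and LRT agree closely for a moderate effect
  set.seed(53)
  etaM <- -0.5 + ifelse(arm == "docetaxel", 0.3, 0) * z
  respM <- rbinom(n, 1, plogis(etaM))
  rw <- testInteraction(z, respM, arm)
  rl <- testInteraction(z, respM, arm, test = "lrt")
  expect_equal(rw$p, rl$p, tolerance = 0.05)
})

test_that("KM restricted mean agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(42)
  for (i in 1:5) {
    n <- 60
    t <- rexp(n, 0.25)
    c <- runif(n, 0, 12)
    time <- pmin(t, c); ev <- as.integer(t <= c)
    tau <- quantile(time, 0.8)
    fit <- survival::survfit(survival::Surv(time, ev) ~ 1)
    want <- unname(survival:::survmean(fit, rmean = tau)$matrix["rmean"])
    expect_equal(kmRMST(time, ev, tau), want, tolerance = 1e-8)
  }
})

test_that("pseudo-observations reduce to min(T, tau) without censoring", {
  set.seed(43)
  t <- rexp(100, 0.3)
  tau <- 5
  ps <- pseudoRMST(t, rep(1L, 100), tau)
  expect_equal(ps, pmin(t, tau), tolerance = 1e-8)
  # intercept-only fit equals mean of min(T, tau)
  r <- rmstRegression(t, rep(1L, 100), z = rep(c(0, 1), 50), tau = tau)
  expect_equal(mean(ps), mean(pmin(t, tau)), tolerance = 1e-10)
})

test_that("uncensored binary-biomarker RMST equals the group mean gap", {
  set.seed(44)
  n <- 150
  grp <- rep(c(0, 1), length.out = n)
  t <- rexp(n, ifelse(grp == 1, 0.15, 0.4))
  tau <- 6
  res <- rmstRegression(t, rep(1L, n), grp, tau = tau)
  want <- mean(pmin(t[grp == 1], tau)) - mean(pmin(t[grp == 0], tau))
  expect_equal(res$estimate, want, tolerance = 1e-6)
  expect_lt(res$p, 0.01)
})

test_that("RMST regression validates tau and events", {
  t <- c(1, 2, 3, 4)
  expect_error(rmstRegression(t, c(1, 1, 1, 1), rnorm(4), tau = 10),
               "tau")
  expect_error(rmstRegression(t, c(0, 0, 0, 0), rnorm(4), tau = 3),
               "events")
})

test_that("robust RMST covariance matches the sandwich estimator", {
  skip_if_not_installed("sandwich")
  set.seed(45)
  n <- 80
  t <- rexp(n, 0.3); c <- runif(n, 0, 8)
  time <- pmin(t, c); ev <- as.integer(t <= c)
  z <- rnorm(n)
  ps <- pseudoRMST(time, ev, tau = 5)
  fit <- lm(ps ~ z)
  seWant <- sqrt(diag(sandwich::vcovHC(fit, type = "HC1")))[["z"]]
  res <- rmstRegression(time, ev, z, tau = 5)
  seGot <- (res$ci_high - res$estimate) / qt(0.975, n - 2)
  expect_equal(seGot, seWant, tolerance = 1e-8)
})

test_that("Wilcoxon exact enumeration matches hand-computed tails", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(10, 11, 12))$p, 0.1)
  same <- wilcoxonRankSum(c(1, 2, 5), c(5, 2, 1))
  expect_equal(same$p, 1)
  # rank invariance under a common monotone transform
  x <- c(0.3, 1.2, 4.4, 2.2); y <- c(0.9, 5.5, 3.1)
  expect_equal(wilcoxonRankSum(x, y)$p,
               wilcoxonRankSum(exp(x), exp(y))$p)
})

test_that("Wilcoxon agrees with wilcox.test in both regimes", {
  set.seed(46)
  # exact regime, no ties
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(wilcoxonRankSum(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # normal approximation with ties
  x <- round(rnorm(30), 1); y <- round(rnorm(25, 0.3), 1)
  expect_equal(wilcoxonRankSum(x, y)$p,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("Kruskal-Wallis/Dunn detects shifts and resists transforms", {
  set.seed(47)
  vals <- c(rnorm(20), rnorm(20), rnorm(20, 10))
  grp <- rep(c("a", "b", "c"), each = 20)
  res <- kruskalDunn(vals, grp)
  expect_lt(res$p, 0.001)
  resT <- kruskalDunn(exp(vals / 5), grp)
  expect_equal(res$H, resT$H, tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 3)
  sigPair <- res$pairwise[res$pairwise$group1 == "a" &
                            res$pairwise$group2 == "c", ]
  expect_lt(sigPair$p, 0.001)
  nullPair <- res$pairwise[res$pairwise$group1 == "a" &
                             res$pairwise$group2 == "b", ]
  expect_gt(nullPair$p, 0.05)
  expect_error(kruskalDunn(vals, rep("a", 60)), "2 groups")
})

test_that("Dunn z follows the pooled-rank formula on a small example", {
  vals <- c(1, 3, 5, 2, 4, 9, 8, 7)
  grp <- c("a", "a", "a", "b", "b", "c", "c", "c")
  res <- kruskalDunn(vals, grp)
  r <- rank(vals)
  N <- 8
  zWant <- (mean(r[1:3]) - mean(r[6:8])) /
    sqrt(N * (N + 1) / 12 * (1 / 3 + 1 / 3))
  got <- res$pairwise[res$pairwise$group1 == "a" &
                        res$pairwise$group2 == "c", "z"]
  expect_equal(got, zWant, tolerance = 1e-12)
})

test_that("Fisher exact matches hypergeometric enumeration", {
  even <- fisherExact2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$or, 1)
  expect_equal(even$p, 1)
  diag <- fisherExact2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(diag$note, "haldane_correction")
  tab <- matrix(c(7, 3, 2, 9), 2)
  expect_equal(fisherExact2x2(tab)$p, fisherExact2x2(t(tab))$p)
  expect_equal(fisherExact2x2(tab)$or, (7 * 9) / (3 * 2))
  expect_error(fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("Spearman matrix matches rank-then-Pearson brute force", {
  x <- c(0.5, 1, 2, 3.5, 7)
  tab <- data.frame(x = x, sq = x^2, neg = -x)
  rho <- spearmanMatrix(tab)
  expect_equal(rho["x", "sq"], 1)
  expect_equal(rho["x", "neg"], -1)
  set.seed(48)
  m <- as.data.frame(matrix(round(rnorm(30), 1), 6, 5))
  got <- spearmanMatrix(m)
  for (i in 1:4) for (j in (i + 1):5) {
    want <- cor(rank(m[[i]]), rank(m[[j]]))
    expect_equal(got[i, j], want, tolerance = 1e-12)
  }
  expect_true(isSymmetric(unname(got)))
  const <- data.frame(a = 1:6, b = rep(2, 6))
  rhoC <- spearmanMatrix(const)
  expect_true(is.na(rhoC["a", "b"]))
  expect_gte(nrow(attr(rhoC, "flagged")), 1)
})

test_that("paired change test handles shifts and zero variance", {
  prim <- setNames(c(1, 2, 3, 4), paste0("p", 1:4))
  rec <- prim + 1
  res <- pairedChangeTest(prim, rec)
  expect_equal(res$mean_change, 1)
  expect_true(is.na(res$p))
  expect_equal(res$note, "zero_variance")
  # invariant to pair ordering
  set.seed(49)
  prim2 <- setNames(rnorm(20), paste0("q", 1:20))
  rec2 <- prim2 + rnorm(20, 0.5, 0.3)
  res1 <- pairedChangeTest(prim2, rec2)
  shuffle <- sample(names(rec2))
  res2 <- pairedChangeTest(prim2, rec2[shuffle])
  expect_equal(res1$mean_change, res2$mean_change, tolerance = 1e-12)
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
  expect_error(pairedChangeTest(prim[1], rec[1]), "2 complete pairs")
})

test_that("balanced random-intercept model equals the paired difference", {
  set.seed(50)
  nPat <- 25
  pat <- rep(sprintf("p%02d", 1:nPat), each = 2)
  tp <- rep(c("primary", "recurrence"), nPat)
  b <- rep(rnorm(nPat, 0, 2), each = 2)
  score <- b + ifelse(tp == "recurrence", 0.8, 0) + rnorm(2 * nPat, 0, 0.5)
  res <- randomInterceptTimepointModel(score, pat, tp)
  pairedDiff <- mean(score[tp == "recurrence"] - score[tp == "primary"])
  expect_equal(res$estimate, pairedDiff, tolerance = 1e-6)
  # translation invariance
  res2 <- randomInterceptTimepointModel(score + 100, pat, tp)
  expect_equal(res$estimate, res2$estimate, tolerance = 1e-8)
})

test_that("degenerate patient variance collapses to ordinary regression", {
  set.seed(51)
  nPat <- 30
  pat <- rep(sprintf("p%02d", 1:nPat), each = 2)
  tp <- rep(c("primary", "recurrence"), nPat)
  score <- ifelse(tp == "recurrence", 0.3, 0) + rnorm(2 * nPat)
  res <- randomInterceptTimepointModel(score, pat, tp)
  expect_lt(res$sigma_patient, 0.3)
  ols <- summary(lm(score ~ factor(tp)))$coefficients[2, ]
  if (res$note == "degenerate_variance")
    expect_equal(res$estimate, unname(ols["Estimate"]), tolerance = 1e-6)
  expect_error(randomInterceptTimepointModel(score, pat,
                                             rep("primary", 60)), "vary")
})

test_that("response rate table reports per-arm rates with Fisher p", {
  lab <- rep(1, 25)
  arm <- rep(c("docetaxel", "carboplatin"), c(8, 17))
  resp <- c(rep(1, 5), rep(0, 3), rep(1, 5), rep(0, 12))
  tab <- responseRateTable(lab, arm, resp)
  expect_equal(tab$rate_docetaxel, 62.5)
  expect_equal(tab$rate_carboplatin, 100 * 5 / 17, tolerance = 1e-9)
  expect_false(is.na(tab$p))
  # conservation and small-cluster flag
  lab2 <- c(rep(1, 21), rep(2, 4))
  tab2 <- responseRateTable(lab2, arm, resp)
  expect_equal(sum(tab2$responders_docetaxel + tab2$responders_carboplatin),
               sum(resp))
  expect_equal(tab2$flag[tab2$cluster == 2], "too_small_to_assess")
  # empty arm within a cluster
  lab3 <- rep(c(1, 2), c(8, 17))  # cluster 1 all docetaxel
  tab3 <- responseRateTable(lab3, arm, resp, minSize = 2)
  expect_true(is.na(tab3$rate_carboplatin[tab3$cluster == 1]))
  expect_equal(tab3$flag[tab3$cluster == 1], "arm_missing")
})
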
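# Association statistics: per-arm logistic models of objective response,
# treatment x biomarker interaction tests, restricted-mean-survival
# regression via pseudo-observations, and the descriptive tests (Wilcoxon,
# Kruskal-Wallis + Dunn, Fisher exact, Spearman, paired t, random-intercept
# timepoint model). All p values are two-sided; no multiplicity adjustment
# is applied unless requested.

.assocRow <- function(biomarker, subgroup, arm, estimate, ciLow, ciHigh, p,
                      n, note = "") {
  data.frame(biomarker = biomarker, subgroup = subgroup, arm = arm,
             estimate = estimate, ci_low = ciLow, ci_high = ciHigh, p = p,
             n = n, note = note, stringsAsFactors = FALSE)
}

.isSeparated <- function(fit) {
  probs <- fitted(fit)
  any(probs < 1e-8) || any(probs > 1 - 1e-8) ||
    any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
}

#' Univariable logistic regression of objective response
#'
#' Fits `response ~ z` by maximum likelihood within an optional subset
#' (typically one treatment arm); the estimate is the log-odds ratio per
#' Z-unit with a Wald confidence interval and two-sided p. Complete or
#' quasi-complete separation is detected and flagged instead of reporting a
#' divergent estimate.
#'
#' @param z numeric biomarker (Z-scored on the full analysis cohort).
#' @param response binary response (0/1).
#' @param subset optional logical/integer subset.
#' @param biomarker,subgroup,arm labels copied into the result row.
#' @param level confidence level.
#' @return one-row data.frame (biomarker, subgroup, arm, estimate, ci_low,
#'   ci_high, p, n, note).
#' @export
fitLogisticORR <- function(z, response, subset = NULL, biomarker = "z",
                           subgroup = "all", arm = "all", level = 0.95) {
  if (!is.null(subset)) {
    z <- z[subset]
    response <- response[subset]
  }
  keep <- complete.cases(z, response)
  z <- z[keep]; response <- response[keep]
  n <- length(z)
  if (sum(response) == 0 || sum(response) == n)
    stop("subset has no responders or no non-responders")
  fit <- suppressWarnings(glm(response ~ z, family = binomial()))
  if (.isSeparated(fit))
    return(.assocRow(biomarker, subgroup, arm, NA, NA, NA, NA, n,
                     note = "separation"))
  est <- coef(fit)["z"]
  se <- sqrt(vcov(fit)["z", "z"])
  zc <- qnorm(1 - (1 - level) / 2)
  .assocRow(biomarker, subgroup, arm, unname(est), unname(est - zc * se),
            unname(est + zc * se), unname(2 * pnorm(-abs(est / se))), n)
}

#' Treatment-by-biomarker interaction test for response
#'
#' Fits `response ~ z + arm + z:arm` and reports the product-term
#' coefficient (difference between the per-arm log-odds ratios) with a
#' two-sided Wald p by default, or a likelihood-ratio p.
#'
#' @param z numeric biomarker.
#' @param response binary response.
#' @param arm two-level treatment factor/character.
#' @param biomarker,subgroup labels for the result row.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return one-row data.frame with `arm = "interaction"`.
#' @export
testInteraction <- function(z, response, arm, biomarker = "z",
                            subgroup = "all", test = c("wald", "lrt")) {
  test <- match.arg(test)
  keep <- complete.cases(z, response, arm)
  z <- z[keep]; response <- response[keep]; arm <- factor(arm[keep])
  if (nlevels(arm) < 2L) stop("both treatment arms must be represented")
  byArm <- tapply(response, arm, function(r) c(sum(r), sum(1 - r)))
  if (any(vapply(byArm, function(x) any(x == 0), logical(1))))
    stop("each arm needs at least one responder and one non-responder")
  fit <- suppressWarnings(glm(response ~ z * arm, family = binomial()))
  cn <- grep(":", names(coef(fit)), value = TRUE)
  est <- coef(fit)[cn]
  se <- sqrt(vcov(fit)[cn, cn])
  note <- if (.isSeparated(fit)) "separation" else ""
  p <- if (test == "wald") {
    2 * pnorm(-abs(est / se))
  } else {
    fit0 <- suppressWarnings(glm(response ~ z + arm, family = binomial()))
    pchisq(fit0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  }
  zc <- qnorm(0.975)
  .assocRow(biomarker, subgroup, "interaction", unname(est),
            unname(est - zc * se), unname(est + zc * se), unname(p),
            length(z), note)
}

.kmRMSTsorted <- function(t, d, tau) {
  # t sorted ascending with events before censorings at ties
  n <- length(t)
  surv <- cumprod(1 - d / (n - seq_len(n) + 1))
  tt <- pmin(t, tau)
  sum(c(1, surv[-n]) * diff(c(0, tt))) + surv[n] * max(0, tau - tt[n])
}

#' Kaplan-Meier restricted mean survival time
#'
#' @param time,event follow-up times and event indicators (1 = event).
#' @param tau truncation horizon.
#' @return the area under the Kaplan-Meier curve up to `tau`.
#' @export
kmRMST <- function(time, event, tau) {
  o <- order(time, -event)
  .kmRMSTsorted(time[o], event[o], tau)
}

#' Jackknife pseudo-observations of the restricted mean survival time
#'
#' `pseudo_i = n * rmst - (n - 1) * rmst_{-i}` on the Kaplan-Meier
#' restricted-mean functional; with no censoring these reduce exactly to
#' `min(time_i, tau)`.
#'
#' @inheritParams kmRMST
#' @return numeric vector, one pseudo-observation per sample.
#' @export
pseudoRMST <- function(time, event, tau) {
  n <- length(time)
  o <- order(time, -event)
  ts <- time[o]; ds <- event[o]
  full <- .kmRMSTsorted(ts, ds, tau)
  ps <- numeric(n)
  for (i in seq_len(n))
    ps[o[i]] <- n * full - (n - 1) * .kmRMSTsorted(ts[-i], ds[-i], tau)
  ps
}

.robustLm <- function(formula, data) {
  fit <- lm(formula, data = data)
  X <- model.matrix(fit)
  u <- residuals(fit)
  n <- nrow(X); p <- ncol(X)
  bread <- chol2inv(chol(crossprod(X)))
  meat <- crossprod(X * u)
  V <- bread %*% meat %*% bread * n / (n - p)  # HC1
  se <- setNames(sqrt(diag(V)), colnames(X))
  list(fit = fit, coef = coef(fit), se = se, df = n - p)
}

#' Restricted-mean-survival regression via pseudo-observations
#'
#' Computes jackknife pseudo-observations of the restricted mean at horizon
#' `tau` and regresses them linearly on the Z-scored biomarker (plus arm and
#' arm interaction if `arm` is supplied with `interaction = TRUE`).
#' Coefficients are in months per Z-unit with heteroskedasticity-robust
#' (HC1) confidence intervals and two-sided p values.
#'
#' @param time,event PFS times (months) and event indicators.
#' @param z numeric biomarker.
#' @param tau horizon; default is the minimum over arms (or the whole
#'   subset) of the largest observed time, the standard
#'   identifiability-preserving choice.
#' @param arm optional treatment factor.
#' @param interaction if `TRUE` (requires `arm`), reports the `z:arm`
#'   coefficient instead of the main effect.
#' @param subset optional subset.
#' @param biomarker,subgroup labels for the result row.
#' @return one-row data.frame as in [fitLogisticORR].
#' @export
rmstRegression <- function(time, event, z, tau = NULL, arm = NULL,
                           interaction = FALSE, subset = NULL,
                           biomarker = "z", subgroup = "all") {
  if (!is.null(subset)) {
    time <- time[subset]; event <- event[subset]; z <- z[subset]
    if (!is.null(arm)) arm <- arm[subset]
  }
  keep <- complete.cases(time, event, z)
  time <- time[keep]; event <- event[keep]; z <- z[keep]
  if (!is.null(arm)) arm <- factor(arm[keep])
  if (is.null(tau)) {
    tau <- if (!is.null(arm)) min(tapply(time, arm, max)) else max(time)
  }
  if (tau > max(time)) stop("tau exceeds maximum follow-up in subset")
  if (sum(event[time <= tau]) == 0) stop("no events before tau")
  ps <- pseudoRMST(time, event, tau)
  dat <- data.frame(ps = ps, z = z)
  armLabel <- "all"
  if (!is.null(arm) && interaction) {
    dat$arm <- arm
    rl <- .robustLm(ps ~ z * arm, dat)
    cn <- grep(":", names(rl$coef), value = TRUE)
    armLabel <- "interaction"
  } else {
    rl <- .robustLm(ps ~ z, dat)
    cn <- "z"
  }
  est <- rl$coef[cn]
  se <- rl$se[cn]
  tc <- qt(0.975, rl$df)
  .assocRow(biomarker, subgroup, armLabel, unname(est),
            unname(est - tc * se), unname(est + tc * se),
            unname(2 * pt(-abs(est / se), rl$df)), length(ps))
}

#' Wilcoxon rank-sum test
#'
#' Exact permutation enumeration when the combined sample size is at most
#' `exactMax` (valid under ties); otherwise the tie-corrected normal
#' approximation with continuity correction. The exact two-sided p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))` over all assignments of the
#' pooled values.
#'
#' @param x,y the two samples.
#' @param exactMax maximum combined n for exact enumeration (default 10).
#' @return list with `statistic` (rank sum of `x`), `p` and `method`.
#' @export
wilcoxonRankSum <- function(x, y, exactMax = 10) {
  stopifnot(length(x) > 0, length(y) > 0)
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x); ny <- length(y); N <- nx + ny
  W <- sum(r[seq_len(nx)])
  if (N <= exactMax) {
    sets <- combn(N, nx)
    Ws <- colSums(matrix(r[sets], nrow = nx))
    p <- min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
    return(list(statistic = W, p = p, method = "exact"))
  }
  ties <- table(r)
  mu <- nx * (N + 1) / 2
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  dev <- W - mu
  dev <- dev - sign(dev) * 0.5  # continuity correction
  zstat <- dev / sqrt(sigma2)
  list(statistic = W, p = min(1, 2 * pnorm(-abs(zstat))),
       method = "normal")
}

#' Kruskal-Wallis omnibus test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p (via
#' [stats::kruskal.test]) and pairwise Dunn z statistics from the pooled
#' ranks. Pairwise p values are reported unadjusted by default.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 non-empty groups).
#' @param adjust p-adjustment method for the pairwise p values
#'   (see [stats::p.adjust]); `"none"` by default.
#' @return list with `H`, `p` (omnibus) and `pairwise` (data.frame of
#'   group pairs, z, p, p_adjusted).
#' @export
kruskalDunn <- function(values, groups, adjust = "none") {
  keep <- complete.cases(values, groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("at least 2 groups required")
  kw <- kruskal.test(values, groups)
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  levs <- levels(groups)
  pairs <- combn(levs, 2)
  z <- apply(pairs, 2, function(pr) {
    sdij <- sqrt((N * (N + 1) / 12 - tieCorr) *
                   (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    (rbar[pr[1]] - rbar[pr[2]]) / sdij
  })
  pw <- 2 * pnorm(-abs(z))
  list(H = unname(kw$statistic), p = kw$p.value,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = unname(z), p = unname(pw),
                             p_adjusted = p.adjust(unname(pw),
                                                   method = adjust)))
}

#' Fisher exact test on a 2x2 table
#'
#' Conditional hypergeometric two-sided p (sum of tables with probability
#' at most the observed one). The odds ratio is the sample cross-product
#' ratio; when a cell is zero, a Haldane correction of +0.5 is added to all
#' cells and flagged.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `or`, `p` and `note`.
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  p <- fisher.test(tab)$p.value
  note <- ""
  t2 <- tab
  if (any(tab == 0)) {
    t2 <- tab + 0.5
    note <- "haldane_correction"
  }
  list(or = (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1]), p = p,
       note = note)
}

#' Pairwise Spearman correlation matrix
#'
#' Pairwise-complete tie-corrected Spearman rho between the continuous
#' columns of a score table; symmetric with unit diagonal. Cells with fewer
#' than 3 complete pairs or a constant column are set to `NA` and listed in
#' the `"flagged"` attribute.
#'
#' @param scores data.frame or matrix of scores; non-numeric columns are
#'   dropped.
#' @return correlation matrix with attribute `"flagged"`.
#' @export
spearmanMatrix <- function(scores) {
  if (is.data.frame(scores))
    scores <- scores[vapply(scores, is.numeric, logical(1))]
  m <- as.matrix(scores)
  stopifnot(ncol(m) >= 2L)
  rho <- suppressWarnings(cor(m, method = "spearman",
                              use = "pairwise.complete.obs"))
  for (i in seq_len(ncol(m)))
    for (j in seq_len(ncol(m)))
      if (sum(complete.cases(m[, i], m[, j])) < 3L) rho[i, j] <- NA
  diag(rho)[!is.na(diag(rho))] <- 1
  flagged <- which(is.na(rho) & upper.tri(rho), arr.ind = TRUE)
  attr(rho, "flagged") <- flagged
  rho
}

#' Paired primary-to-recurrence change test
#'
#' Paired t test on per-patient differences (recurrence minus primary),
#' matched by the names of the two vectors. A zero-variance difference
#' vector returns the mean change with an undefined p, flagged.
#'
#' @param primary,recurrence named numeric vectors (names = patient ids).
#' @return list with `mean_change`, `p`, `n_pairs`, `note`.
#' @export
pairedChangeTest <- function(primary, recurrence) {
  ids <- intersect(names(primary), names(recurrence))
  if (length(ids) < 2L) stop("at least 2 complete pairs required")
  d <- recurrence[ids] - primary[ids]
  if (sd(d) == 0)
    return(list(mean_change = mean(d), p = NA_real_, n_pairs = length(d),
                note = "zero_variance"))
  tt <- t.test(d)
  list(mean_change = unname(mean(d)), p = tt$p.value, n_pairs = length(d),
       note = "")
}

#' Random-intercept model of score change by timepoint
#'
#' Gaussian mixed model `score ~ timepoint + (1 | patient)` fitted by REML,
#' accommodating patients with multiple recurrence/metastatic samples. The
#' reported effect is the fixed timepoint coefficient (second level vs
#' first) with a two-sided Wald p. A degenerate patient variance (singular
#' fit) collapses to ordinary regression and is flagged.
#'
#' @param score numeric outcome (a signature score).
#' @param patientId patient identifier per sample.
#' @param timepoint two-level factor/character (e.g. primary/recurrence);
#'   ordered so the second level is the later timepoint.
#' @return list with `estimate`, `se`, `p`, `sigma_patient`, `note`.
#' @export
randomInterceptTimepointModel <- function(score, patientId, timepoint) {
  timepoint <- factor(timepoint)
  if (nlevels(timepoint) < 2L) stop("timepoint must vary")
  patientId <- factor(patientId)
  if (nlevels(patientId) < 2L) stop("at least 2 patients required")
  both <- tapply(as.integer(timepoint), patientId,
                 function(x) length(unique(x)))
  if (!any(both >= 2)) stop("no patient observed at both timepoints")
  dat <- data.frame(score = score, patientId = patientId,
                    timepoint = timepoint)
  fit <- suppressMessages(lme4::lmer(
    score ~ timepoint + (1 | patientId), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  cf <- lme4::fixef(fit)[2]
  se <- sqrt(vcov(fit)[2, 2])
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigmaPatient <- vc$sdcor[vc$grp == "patientId"]
  note <- if (lme4::isSingular(fit)) "degenerate_variance" else ""
  list(estimate = unname(cf), se = unname(se),
       p = unname(2 * pnorm(-abs(cf / se))),
       sigma_patient = sigmaPatient, note = note)
}

#' Per-cluster per-arm response rates with Fisher comparisons
#'
#' @param labels cluster label per sample.
#' @param arm treatment arm per sample.
#' @param response binary response per sample.
#' @param minSize clusters smaller than this are reported but flagged
#'   `"too_small_to_assess"` and not tested.
#' @return data.frame with one row per cluster: per-arm responders, treated
#'   counts and rates (percent), Fisher p for the arm contrast, and a flag.
#' @export
responseRateTable <- function(labels, arm, response, minSize = 10L) {
  stopifnot(length(labels) == length(arm), length(arm) == length(response))
  arms <- sort(unique(as.character(arm)))
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    idx <- labels == cl
    row <- data.frame(cluster = cl, n = sum(idx))
    counts <- matrix(0L, 2, 2)
    for (ai in seq_along(arms)) {
      sel <- idx & arm == arms[ai]
      nResp <- sum(response[sel]); nTot <- sum(sel)
      counts[ai, ] <- c(nResp, nTot - nResp)
      row[[paste0("responders_", arms[ai])]] <- nResp
      row[[paste0("treated_", arms[ai])]] <- nTot
      row[[paste0("rate_", arms[ai])]] <-
        if (nTot > 0) 100 * nResp / nTot else NA_real_
    }
    row$p <- NA_real_
    row$flag <- ""
    if (sum(idx) < minSize) {
      row$flag <- "too_small_to_assess"
    } else if (any(rowSums(counts) == 0)) {
      row$flag <- "arm_missing"
    } else if (any(colSums(counts) == 0)) {
      row$flag <- "degenerate_response"
    } else {
      row$p <- fisherExact2x2(counts)$p
    }
    row
  }))
  rownames(out) <- NULL
  out
}
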
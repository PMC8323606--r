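# Group statistics: t-tests, BH-FDR, partial Pearson, regression slopes.

.new_test_result <- function(statistic, p, n, estimate, ci = c(NA, NA),
                             method = "") {
  structure(list(statistic = statistic, p = p, q_adjusted = NA_real_,
                 n = n, estimate = estimate, ci = ci, method = method),
            class = "na_test_result")
}

#' @export
print.na_test_result <- function(x, ...) {
  cat(sprintf("<na_test_result %s>  stat=%.4g  p=%.4g  n=%d  estimate=%.4g\n",
              x$method, x$statistic, x$p, x$n, x$estimate))
  invisible(x)
}

#' Two-sample t-test (Welch by default, pooled-variance optional)
#'
#' @param groupA,groupB numeric vectors (n >= 2 each)
#' @param pooled use the pooled-variance (equal variance) Student t instead
#'   of Welch
#' @return `na_test_result` with the mean difference A - B as estimate
#' @export
unpaired_t <- function(groupA, groupB, pooled = FALSE) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 observations")
  tt <- t.test(groupA, groupB, var.equal = pooled)
  .new_test_result(unname(tt$statistic), tt$p.value,
                   length(groupA) + length(groupB),
                   mean(groupA) - mean(groupB), unname(tt$conf.int),
                   if (pooled) "pooled t" else "Welch t")
}

#' Paired t-test
#'
#' @param x,y paired numeric vectors of equal length (n >= 2 pairs)
#' @return `na_test_result` with the mean difference x - y as estimate
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("pairs must be complete")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (sd(x - y) == 0)
    stop("degenerate pairing: zero variance of differences")
  tt <- t.test(x, y, paired = TRUE)
  .new_test_result(unname(tt$statistic), tt$p.value, length(x),
                   mean(x - y), unname(tt$conf.int), "paired t")
}

#' Benjamini-Hochberg false discovery rate step-up
#'
#' @param pvalues numeric vector of p-values in [0, 1]
#' @param q FDR threshold (default 0.05; the exploratory analyses use 0.2)
#' @return data.frame with `p`, `q_adjusted` (monotone BH-adjusted values)
#'   and `reject`
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must be in [0, 1]")
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  adj <- p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, q_adjusted = adj, reject = adj <= q)
}

#' Partial Pearson correlation controlling for covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after linear
#' regression on the covariates (e.g. age and sex); the p-value uses a
#' t-distribution with `n - 2 - ncol(covariates)` degrees of freedom.  With
#' no covariates this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors
#' @param covariates data.frame / matrix of covariates (may be NULL)
#' @return `na_test_result` with r as estimate
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  ncov <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n <= ncov + 2) stop("need n > number of covariates + 2")
  if (ncov > 0) {
    Z <- as.matrix(as.data.frame(covariates))
    if (qr(cbind(1, Z))$rank < ncov + 1) stop("rank-deficient covariates")
    x <- residuals(lm(x ~ Z))
    y <- residuals(lm(y ~ Z))
  }
  r <- cor(x, y)
  df <- n - 2 - ncov
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  .new_test_result(tstat, p, n, r,
                   method = if (ncov) "partial Pearson" else "Pearson")
}

#' Ordinary least squares slope with 95% confidence interval
#'
#' Reports slope and intercept with the half-width of their 95% CIs in the
#' `slope_pm` / `intercept_pm` fields (the "value +/- hw" style used for
#' regression results).
#'
#' @param x,y numeric vectors (n >= 3)
#' @return list with `slope`, `slope_pm`, `intercept`, `intercept_pm`,
#'   `slope_ci`, `intercept_ci`, `r`, `p_slope`, `n`
#' @export
regression_slope <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need n >= 3")
  if (sd(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  ci <- suppressWarnings(confint(fit, level = 0.95))
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       slope_pm = unname(diff(ci[2, ]) / 2),
       intercept = unname(coef(fit)[1]),
       intercept_pm = unname(diff(ci[1, ]) / 2),
       slope_ci = unname(ci[2, ]), intercept_ci = unname(ci[1, ]),
       r = sign(coef(fit)[2]) * sqrt(sm$r.squared),
       p_slope = unname(sm$coefficients[2, 4]),
       n = length(x))
}

#' Group comparison of cohort ROI intensities with BH-FDR
#'
#' For every sequence x region, tests patients vs controls with an unpaired
#' t-test and applies Benjamini-Hochberg FDR within each sequence family.
#'
#' @param cohort data.frame from [simulate_cohort()]
#' @param q FDR threshold
#' @param pooled passed to [unpaired_t()]
#' @return data.frame: sequence, region, t, p, q_adjusted, reject,
#'   mean_patient, mean_control
#' @export
cohort_group_tests <- function(cohort, q = 0.05, pooled = FALSE) {
  out <- list()
  for (sq in unique(cohort$sequence)) {
    sub <- cohort[cohort$sequence == sq, ]
    ctrl_wm <- sub[sub$group == "control" & sub$region != "lesion", ]
    ctrl_by_subj <- tapply(ctrl_wm$intensity, ctrl_wm$subject, mean)
    res <- list()
    for (reg in setdiff(unique(sub$region), character(0))) {
      pat <- sub[sub$group == "patient" & sub$region == reg, "intensity"]
      if (length(pat) < 2) next
      tt <- unpaired_t(pat, as.numeric(ctrl_by_subj), pooled = pooled)
      res[[length(res) + 1L]] <- data.frame(
        sequence = sq, region = reg, t = tt$statistic, p = tt$p,
        mean_patient = mean(pat), mean_control = mean(ctrl_by_subj))
    }
    res <- do.call(rbind, res)
    fdr <- bh_fdr(res$p, q = q)
    res$q_adjusted <- fdr$q_adjusted
    res$reject <- fdr$reject
    out[[length(out) + 1L]] <- res
  }
  do.call(rbind, out)
}
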
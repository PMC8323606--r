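# Group statistics: t-tests, BH-FDR, partial correlation, regression.

test_that("t-tests match the textbook formulas", {
  set.seed(1)
  a <- rnorm(12, 1, 2); b <- rnorm(9, 0.2, 1.5)
  # pooled-variance oracle from the definition
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_pool <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  res <- unpaired_t(a, b, pooled = TRUE)
  expect_equal(res$statistic, t_pool)
  expect_equal(res$p, 2 * pt(-abs(t_pool), length(a) + length(b) - 2))
  # Welch oracle
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  t_w <- (mean(a) - mean(b)) / se
  expect_equal(unpaired_t(a, b)$statistic, t_w)

  d <- rnorm(10)
  expect_equal(paired_t(d + 5, rep(5, 10))$statistic,
               mean(d) / (sd(d) / sqrt(10)))
  expect_equal(paired_t(a[1:9], b)$statistic,
               mean(a[1:9] - b) / (sd(a[1:9] - b) / 3))
})

test_that("identical groups give t = 0, p = 1; degenerate inputs error", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  res <- unpaired_t(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(unpaired_t(1, c(1, 2)), "at least 2")
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "degenerate")
  expect_error(paired_t(c(1, 2), c(1, 2, 3)), "complete")
})

test_that("BH step-up matches the hand-evaluated rule", {
  p <- c(0.01, 0.02, 0.04, 0.9)
  # by hand: sorted p(k) vs k/m * q at q = 0.05 -> largest k with
  # p(k) <= k/4 * 0.05 is k = 2; adjusted = cummin from the top of
  # p(k)*m/k = (0.04, 0.04, 0.0533, 0.9)
  res <- bh_fdr(p, q = 0.05)
  expect_equal(res$q_adjusted, c(0.04, 0.04, 0.04 * 4 / 3, 0.9))
  expect_equal(res$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(res$q_adjusted >= res$p))
  # monotone in rank
  expect_true(all(diff(res$q_adjusted[order(res$p)]) >= 0))

  expect_equal(bh_fdr(0.03)$q_adjusted, 0.03)  # single p unchanged
  expect_true(all(bh_fdr(rep(0, 5))$reject))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("rejections under a larger q are a superset", {
  set.seed(3)
  p <- runif(30)^2
  r1 <- bh_fdr(p, q = 0.05)$reject
  r2 <- bh_fdr(p, q = 0.20)$reject
  expect_true(all(r2[r1]))
})

test_that("partial correlation equals the residualize-then-correlate
           oracle", {
  set.seed(7)
  n <- 40
  age <- runif(n, 20, 70); sex <- rbinom(n, 1, 0.5)
  x <- 0.02 * age + 0.3 * sex + rnorm(n)
  y <- -0.01 * age + 0.1 * sex + 0.5 * x + rnorm(n)
  Z <- cbind(age, sex)
  rx <- residuals(lm(x ~ age + sex))
  ry <- residuals(lm(y ~ age + sex))
  r_oracle <- cor(rx, ry)
  res <- partial_pearson(x, y, data.frame(age, sex))
  expect_equal(res$estimate, r_oracle, tolerance = 1e-10)
  df <- n - 4
  t_oracle <- r_oracle * sqrt(df / (1 - r_oracle^2))
  expect_equal(res$p, 2 * pt(-abs(t_oracle), df), tolerance = 1e-12)
})

test_that("partial correlation degenerates gracefully", {
  set.seed(8)
  x <- rnorm(20); z <- rnorm(20)
  expect_equal(partial_pearson(x, 2 * x + 1, data.frame(z))$estimate, 1,
               tolerance = 1e-12)
  expect_equal(partial_pearson(x, z)$estimate, cor(x, z))
  expect_error(partial_pearson(x, z, data.frame(z, z2 = 2 * z)),
               "rank-deficient")
  expect_error(partial_pearson(x[1:3], z[1:3], data.frame(z = z[1:3],
                                                          w = x[1:3])),
               "covariates")
})

test_that("covariates orthogonal to both variables leave the correlation
           unchanged", {
  set.seed(9)
  n <- 64
  x <- rnorm(n); y <- rnorm(n)
  x <- x - mean(x); y <- y - mean(y)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x + y))  # orthogonalize z to x and y
  plain <- partial_pearson(x, y)$estimate
  part <- partial_pearson(x, y, data.frame(z))$estimate
  expect_equal(part, plain, tolerance = 1e-10)
})

test_that("regression slope matches the closed-form OLS oracle", {
  x <- c(1, 2, 3, 4, 5)
  res <- suppressWarnings(regression_slope(x, 2 * x))  # exact fit
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  expect_equal(res$slope_pm, 0, tolerance = 1e-10)

  set.seed(10)
  xr <- rnorm(30); yr <- 1.5 * xr + rnorm(30, 0, 0.7)
  b1 <- sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
  b0 <- mean(yr) - b1 * mean(xr)
  resid <- yr - b0 - b1 * xr
  se_b1 <- sqrt(sum(resid^2) / 28 / sum((xr - mean(xr))^2))
  r2 <- regression_slope(xr, yr)
  expect_equal(r2$slope, b1)
  expect_equal(r2$intercept, b0)
  expect_equal(r2$slope_pm, qt(0.975, 28) * se_b1, tolerance = 1e-10)
  expect_error(regression_slope(rep(1, 5), rnorm(5)), "variance")
})

test_that("lesion-contrast regression across a simulated cohort recovers
           the true sequence-effect ratio", {
  rw <- full_weightings()
  concs <- sodium_concentrations()
  states <- c("control", "nawm", "lesion")
  base <- sapply(c("NaDW", "NaPACMAN"), function(sq)
    setNames(vapply(states, function(st)
      naContrast:::.state_signal(st, sq, rw, concs), numeric(1)), states))
  true_ratio <- (base["lesion", "NaPACMAN"] / base["nawm", "NaPACMAN"] - 1) /
    (base["lesion", "NaDW"] / base["nawm", "NaDW"] - 1)
  covered <- 0
  n_rep <- 40
  for (k in seq_len(n_rep)) {
    co <- simulate_cohort(n_controls = 4, n_patients = 30,
                          sequences = c("NaDW", "NaPACMAN"),
                          regions = "scc", noise_sd = 0.002,
                          seed = 100 + k)
    pat <- co[co$group == "patient", ]
    relimat <- sapply(c("NaDW", "NaPACMAN"), function(sq) {
      s <- pat[pat$sequence == sq, ]
      les <- s[s$region == "lesion", "intensity"]
      nawm <- s[s$region == "scc", "intensity"]
      les / nawm - 1
    })
    fit <- regression_slope(relimat[, "NaDW"], relimat[, "NaPACMAN"])
    if (fit$slope_ci[1] <= true_ratio && true_ratio <= fit$slope_ci[2])
      covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.9)
  expect_equal(true_ratio, 1.5, tolerance = 0.15)
})

test_that("cohort group tests reject the lesion elevation but not the null
           regions", {
  co <- simulate_cohort(seed = 31)
  gt <- cohort_group_tests(co, q = 0.05)
  expect_true(gt$reject[gt$sequence == "NaDW" & gt$region == "lesion"])
  expect_true(gt$reject[gt$sequence == "NaPACMAN" & gt$region == "lesion"])
  expect_true(all(gt$q_adjusted >= gt$p))
})
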
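test_that("gated omnibus takes the ANOVA route on clean normal data", {
  set.seed(1)
  g <- rep(c("A", "B", "C"), each = 40)
  x <- rnorm(120) + rep(c(0, 0, 1), each = 40)
  res <- omnibusThreeGroup(x, g)
  expect_equal(res@route, "anova")
  # oracle: textbook F from group sufficient statistics
  ni <- tapply(x, g, length); mi <- tapply(x, g, mean); vi <- tapply(x, g, var)
  gm <- mean(x)
  msb <- sum(ni * (mi - gm)^2) / 2
  msw <- sum((ni - 1) * vi) / (length(x) - 3)
  expect_equal(unname(res@statistic["F"]), msb / msw, tolerance = 1e-10)
  expect_equal(res@df, c(2, 117))
})

test_that("identical group patterns give F ~ 0 and p ~ 1", {
  x <- rep(c(-1, 0, 1), times = 30)
  g <- rep(c("A", "B", "C"), each = 30)
  res <- omnibusThreeGroup(x, g)
  expect_lt(unname(res@statistic[1]), 1e-10)
  expect_gt(res@p, 0.999)
  expect_error(omnibusThreeGroup(rep(1, 9), g = rep(c("A", "B", "C"), 3)),
               "zero within-group variance")
})

test_that("skewed data route to Kruskal-Wallis in almost all replicates", {
  routes <- vapply(1:200, function(s) {
    set.seed(s)
    x <- rlnorm(90, 0, 1.5)
    omnibusThreeGroup(x, rep(c("A", "B", "C"), each = 30))@route
  }, character(1))
  expect_gte(mean(routes == "kruskal_wallis"), 0.95)
})

test_that("post hoc p-values are BH-adjusted as the step-up formula dictates", {
  expect_equal(oracleBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))
    expect_equal(p.adjust(p, "BH"), oracleBH(p), tolerance = 1e-15)
  }
  # monotone in the raw-p order, never exceeding 1
  set.seed(1)
  p <- runif(6)
  adj <- oracleBH(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj <= 1) && all(adj >= p))
})

test_that("pairwise post hocs behave on identical and separated groups", {
  set.seed(2)
  x <- c(rnorm(30), rnorm(30), rnorm(30) + 3)
  g <- rep(c("A", "B", "C"), each = 30)
  res <- posthocPairwise(x, g, "anova")
  expect_equal(nrow(res@posthoc), 3L)
  expect_true(all(res@posthoc$p_adj >= res@posthoc$p_raw - 1e-12))
  same <- res@posthoc[res@posthoc$comparison == "B-A", ]
  expect_gt(same$p_raw, 0.5)                     # two identical groups
  kw <- posthocPairwise(x, g, "kruskal_wallis")  # Dunn z on midranks
  expect_equal(nrow(kw@posthoc), 3L)
  expect_lt(kw@posthoc$p_adj[grepl("C", kw@posthoc$comparison)][1], 0.01)
  expect_error(posthocPairwise(x[1:30], g[1:30], "anova"), "two groups")
})

test_that("covariate-adjusted group effects are recovered", {
  set.seed(7)
  grp <- rep(c("DMNC", "DMMCI"), each = 38)
  z <- rnorm(76)
  y <- 0.12 * (grp == "DMMCI") + 0.5 * z + rnorm(76, 0, 0.01)
  res <- ancovaGroupEffect(y, grp, data.frame(z = z))
  # reference level is alphabetical (DMMCI), so the DMNC coefficient is -0.12
  expect_equal(abs(res@effect$coefficient), 0.12, tolerance = 0.01 / 0.12)
  # oracle: independent normal-equations solve
  X <- cbind(1, grp == "DMNC", z)   # factor level order: DMMCI reference
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(abs(res@effect$coefficient), abs(beta[2]), tolerance = 1e-10)
  # outcome identical to a covariate: group effect vanishes
  res0 <- suppressWarnings(ancovaGroupEffect(z, grp, data.frame(z = z)))
  expect_lt(abs(res0@effect$coefficient), 1e-12)
  expect_error(ancovaGroupEffect(y, grp, data.frame(z = z, z2 = z)),
               "collinear")
})

test_that("logistic OR on a 2x2 design equals the cross-product ratio", {
  # exposure/outcome counts a=20 b=10 c=10 d=20
  x <- c(rep(1, 30), rep(0, 30))
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  res <- logisticOr(y, x)
  expect_equal(res@effect$OR, (20 * 20) / (10 * 10), tolerance = 1e-6)
  expect_error(logisticOr(rep(1, 10), rnorm(10)), "both classes")
  sep <- logisticOr
  expect_error(sep(c(rep(0, 10), rep(1, 10)), c(rnorm(10), rnorm(10) + 50)),
               "separation")
})

test_that("logistic CIs cover the null under independence", {
  covered <- vapply(1:200, function(s) {
    set.seed(s)
    y <- rbinom(80, 1, 0.5)
    x <- rnorm(80)
    ci <- logisticOr(y, x)@effect$ci
    ci[1] <= 1 && 1 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("percent-form scaling gives the OR per 0.01 increment", {
  set.seed(3)
  x <- rnorm(100, 1.6, 0.2)
  y <- rbinom(100, 1, plogis(-3 * (x - 1.6)))
  a <- logisticOr(y, x, scalePercent = FALSE)
  b <- logisticOr(y, x, scalePercent = TRUE)
  expect_equal(b@effect$coefficient, a@effect$coefficient / 100,
               tolerance = 1e-8)
  expect_equal(b@p, a@p, tolerance = 1e-8)
})

test_that("partial correlation equals the residual-Pearson oracle", {
  # 10-row fixture: x and y both linear in z plus independent noise
  z <- c(0.2, 0.9, 1.7, 2.1, 3.4, 4.2, 4.8, 5.9, 6.6, 7.3)
  x <- 2 * z + c(0.12, -0.31, 0.05, 0.22, -0.18, 0.07, -0.25, 0.14, 0.02, -0.09)
  y <- -z + c(-0.21, 0.11, 0.31, -0.05, 0.19, -0.27, 0.08, -0.13, 0.24, -0.02)
  res <- partialCorrelation(x, y, data.frame(z = z))
  # brute-force residualization oracle
  Z <- cbind(1, z)
  H <- Z %*% solve(t(Z) %*% Z) %*% t(Z)
  rOracle <- cor((diag(10) - H) %*% x, (diag(10) - H) %*% y)
  expect_equal(res@effect$r, drop(rOracle), tolerance = 1e-12)
  expect_lt(abs(res@effect$r), abs(cor(x, y)))  # marginal r is inflated by z
  expect_equal(res@df, 10 - 2 - 1)
  # no covariates: plain Pearson
  res0 <- partialCorrelation(x, y)
  expect_equal(res0@effect$r, cor(x, y), tolerance = 1e-14)
  # y = x gives r = 1; constant residuals are an error
  expect_equal(partialCorrelation(x, x, data.frame(z = z))@effect$r, 1,
               tolerance = 1e-12)
  expect_error(partialCorrelation(z, y, data.frame(z = z)), "constant")
})

test_that("partial correlation matches the oracle on random fuzz cases", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(15:40, 1)
    k <- sample(1:3, 1)
    Zc <- matrix(rnorm(n * k), n)
    x <- rnorm(n) + Zc %*% rnorm(k)
    y <- rnorm(n) + Zc %*% rnorm(k)
    res <- partialCorrelation(drop(x), drop(y), as.data.frame(Zc))
    Z <- cbind(1, Zc)
    H <- Z %*% solve(t(Z) %*% Z) %*% t(Z)
    rOracle <- drop(cor((diag(n) - H) %*% x, (diag(n) - H) %*% y))
    expect_equal(res@effect$r, rOracle, tolerance = 1e-12)
  }
})

test_that("two-sample comparison gates between t and Mann-Whitney", {
  x <- rep(c(4.9, 5.0, 5.1), 4)
  g <- rep(c("a", "b"), each = 6)
  res <- twoSampleCompare(x, g)
  expect_gt(res@p, 0.99)
  # printed 6+6 fixture: t equals the hand-computed pooled-variance formula
  a <- c(5.1, 4.8, 5.6, 5.0, 4.9, 5.3)
  b <- c(6.0, 5.7, 6.3, 5.9, 6.1, 5.8)
  res2 <- twoSampleCompare(c(a, b), rep(c("a", "b"), each = 6))
  sp <- sqrt((5 * var(a) + 5 * var(b)) / 10)
  tOracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 6 + 1 / 6))
  expect_equal(abs(unname(res2@statistic["t"])), abs(tOracle),
               tolerance = 1e-10)
  expect_equal(res2@route, "t_test")
  routes <- vapply(1:100, function(s) {
    set.seed(s)
    twoSampleCompare(rlnorm(60, 0, 1.5), rep(c("a", "b"), each = 30))@route
  }, character(1))
  expect_gte(mean(routes == "mann_whitney"), 0.95)
  expect_error(twoSampleCompare(x, rep("a", 12)), "two groups")
})

test_that("chi-square reproduces the reconstructed gender-by-group table", {
  counts <- rbind(male = c(11, 15, 19), female = c(26, 22, 20))
  res <- chiSquareCounts(counts)
  expect_equal(unname(res@statistic["X2"]), 2.868, tolerance = 0.001 / 2.868)
  expect_equal(res@df, 2)
  # perfectly proportional table
  prop <- rbind(c(10, 20, 30), c(5, 10, 15))
  expect_lt(unname(chiSquareCounts(prop)@statistic[1]), 1e-12)
  # 2x2 closed form: X2 = (ad-bc)^2 N / (r1 r2 c1 c2)
  set.seed(6)
  for (i in 1:20) {
    m <- matrix(sample(5:40, 4, replace = TRUE), 2)
    closed <- (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 * sum(m) /
      (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
    expect_equal(unname(chiSquareCounts(m)@statistic[1]), closed,
                 tolerance = 1e-10)
  }
  expect_error(chiSquareCounts(rbind(c(0, 0), c(1, 2))), "positive")
})

test_that("gated omnibus type-I error is controlled on null data", {
  rejected <- vapply(1:500, function(s) {
    set.seed(s)
    omnibusThreeGroup(rnorm(60), rep(c("A", "B", "C"), each = 20))@p < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.02)
  expect_lte(mean(rejected), 0.08)
})

test_that("the full stats roster has the documented keys and gates per column", {
  spec <- smokePhantomSpec()
  cv <- truthAsMeasured(generateCohort(
    studyPresets(), c(HC = 13L, DMNC = 13L, DMMCI = 13L), spec, smallScheme(),
    seed = 5, keepImaging = FALSE, imaging = FALSE)$covariates)
  report <- runFullStats(cv)
  expect_identical(names(report), fullStatsKeys())
  expect_s4_class(report$alps_omnibus_mean, "StatResult")
  expect_true(all(vapply(report, function(r) r@p[1] >= 0 && r@p[1] <= 1,
                         logical(1))))
  expect_equal(report$table1_gender@route, "chi_square")
  expect_equal(report$table1_duration@route, "kruskal_wallis")
  expect_true(report$logistic_mci_mean@route == "logistic")
  expect_true(report$pcorr_all_mean_MoCA@route == "partial_correlation")
  # missing columns are reported by name
  expect_error(runFullStats(cv[, setdiff(names(cv), "alps_left")]),
               "alps_left")
})

test_that("null cohorts yield few BH-significant post hocs", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    x <- rnorm(111)
    g <- rep(c("A", "B", "C"), each = 37)
    omni <- omnibusThreeGroup(x, g)
    ph <- posthocPairwise(x, g, omni@route)
    mean(ph@posthoc$p_adj < 0.05)
  }, numeric(1))
  expect_lte(mean(hits), 0.05)
})
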
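# Cohort-level statistical chain: assumption-gated omnibus tests with
# FDR-adjusted post hocs, covariate-adjusted linear models, binary logistic
# regression, partial correlations and count tests.

statResult <- function(test, route, statistic, df, p,
                       posthoc = data.frame(), effect = list(),
                       notes = character()) {
  new("StatResult", test = test, route = route, statistic = statistic,
      df = as.numeric(df), p = as.numeric(p), posthoc = posthoc,
      effect = effect, notes = notes)
}

# Shapiro-Wilk per group (constant or too-small groups count as failing
# normality) and Levene's test centered on the mean, both at alpha.
gateAssumptions <- function(values, groups, alpha = 0.05) {
  normal <- vapply(split(values, groups), function(v) {
    if (length(v) < 3 || length(v) > 5000 || var(v) == 0) return(FALSE)
    shapiro.test(v)$p.value >= alpha
  }, logical(1))
  homo <- tryCatch({
    lev <- car::leveneTest(values ~ factor(groups), center = mean)
    lev[["Pr(>F)"]][1] >= alpha
  }, error = function(e) FALSE)
  list(normal = normal, homogeneous = homo, pass = all(normal) && homo)
}

#' Assumption-gated three-group omnibus test
#'
#' Shapiro-Wilk normality per group and Levene's homogeneity test (centered
#' on the mean), both at alpha = 0.05, gate the route: one-way ANOVA when all
#' pass, Kruskal-Wallis (midrank tie handling) otherwise. The route taken is
#' recorded in the result.
#'
#' @param values numeric vector of per-subject measurements.
#' @param groups group labels, three levels with n >= 3 each.
#' @param alpha gate level for both assumption tests.
#' @return a [StatResult-class] (no post hoc; see [posthocPairwise()]).
#' @export
omnibusThreeGroup <- function(values, groups, alpha = 0.05) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) != 3) stop("exactly three groups are required")
  if (any(table(groups) < 3)) stop("every group needs n >= 3")
  if (all(vapply(split(values, groups), var, numeric(1)) == 0))
    stop("zero within-group variance in every group")
  gate <- gateAssumptions(values, groups, alpha)
  notes <- sprintf("gate: normal=%s homogeneous=%s",
                   paste(gate$normal, collapse = "/"), gate$homogeneous)
  if (gate$pass) {
    fit <- aov(values ~ groups)
    s <- summary(fit)[[1]]
    statResult("three-group omnibus", "anova",
               c(F = s[["F value"]][1]), df = s[["Df"]],
               p = s[["Pr(>F)"]][1], notes = notes)
  } else {
    kt <- kruskal.test(values, groups)
    statResult("three-group omnibus", "kruskal_wallis",
               c(H = unname(kt$statistic)), df = unname(kt$parameter),
               p = kt$p.value, notes = notes)
  }
}

# Dunn's z-tests on midranks with tie-corrected variance.
dunnTest <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)            # midranks
  Rbar <- tapply(r, groups, mean)
  n <- table(groups)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  cmp <- utils::combn(lev, 2)
  out <- lapply(seq_len(ncol(cmp)), function(k) {
    a <- cmp[1, k]; b <- cmp[2, k]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (Rbar[[a]] - Rbar[[b]]) / se
    data.frame(comparison = paste(a, "-", b), estimate = Rbar[[a]] - Rbar[[b]],
               statistic = z, p_raw = 2 * pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise post hoc comparisons with BH correction
#'
#' Tukey's HSD after an ANOVA route, Dunn's midrank z-tests after a
#' Kruskal-Wallis route; the pairwise p-values are then Benjamini-Hochberg
#' adjusted within the family, and both raw and adjusted values are reported.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 levels).
#' @param route "anova" or "kruskal_wallis", normally the route recorded by
#'   [omnibusThreeGroup()].
#' @return a [StatResult-class] whose \code{posthoc} table has columns
#'   comparison, estimate, statistic, p_raw, p_adj.
#' @export
posthocPairwise <- function(values, groups, route = c("anova", "kruskal_wallis")) {
  route <- match.arg(route)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2) stop("at least two groups are required")
  if (route == "anova") {
    tk <- TukeyHSD(aov(values ~ groups))$groups
    ph <- data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                     statistic = NA_real_, p_raw = tk[, "p adj"],
                     stringsAsFactors = FALSE)
  } else {
    ph <- dunnTest(values, groups)
  }
  ph$p_adj <- p.adjust(ph$p_raw, method = "BH")
  rownames(ph) <- NULL
  statResult("pairwise post hoc", route, statistic = c(n = nrow(ph)),
             df = NA_real_, p = min(ph$p_adj), posthoc = ph)
}

#' Covariate-adjusted two-group comparison (general linear model)
#'
#' Linear model \code{outcome ~ group + covariates} on complete cases;
#' reports the group coefficient with its t/F statistic and p-value.
#'
#' @param outcome numeric vector.
#' @param groups two-level labels.
#' @param covariates data.frame of numeric covariates (rows with missing
#'   values dropped and counted).
#' @param kappaMax condition-number threshold above which the design is
#'   declared collinear.
#' @return a [StatResult-class]; \code{effect$coefficient} is the adjusted
#'   group difference with a 95% CI.
#' @export
ancovaGroupEffect <- function(outcome, groups, covariates, kappaMax = 1e8) {
  groups <- factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  covariates <- as.data.frame(covariates)
  cc <- complete.cases(outcome, groups, covariates)
  dropped <- sum(!cc)
  d <- data.frame(outcome = outcome[cc], group = groups[cc],
                  covariates[cc, , drop = FALSE])
  X <- stats::model.matrix(outcome ~ ., data = d)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear design; offending columns: ", paste(bad, collapse = ", "))
  }
  if (kappa(X, exact = TRUE) > kappaMax)
    stop("ill-conditioned design (condition number above threshold); columns: ",
         paste(colnames(X)[-1], collapse = ", "))
  fit <- lm(outcome ~ ., data = d)
  s <- summary(fit)$coefficients
  row <- grep("^group", rownames(s))[1]
  est <- s[row, "Estimate"]; se <- s[row, "Std. Error"]
  tval <- s[row, "t value"]; p <- s[row, "Pr(>|t|)"]
  dfres <- fit$df.residual
  ci <- est + c(-1, 1) * stats::qt(0.975, dfres) * se
  statResult("covariate-adjusted group difference", "glm",
             c(F = tval^2, t = tval), df = c(1, dfres), p = p,
             effect = list(coefficient = est, ci = ci,
                           reference = levels(groups)[1]),
             notes = sprintf("dropped %d incomplete rows", dropped))
}

#' Binary logistic regression odds ratio
#'
#' Maximum-likelihood logistic fit of a binary outcome on one predictor
#' (optionally multiplied by 100 first, so the OR is per 0.01 increment of a
#' ratio-scale predictor such as the ALPS-index) plus optional covariates.
#' Complete separation is an error, never a silently huge OR.
#'
#' @param outcome binary vector (logical, 0/1 or two-level factor); the
#'   second level / 1 / TRUE is the event.
#' @param predictor numeric vector.
#' @param scalePercent multiply the predictor by 100 before fitting.
#' @param covariates optional data.frame of adjustment covariates.
#' @return a [StatResult-class]; \code{effect$OR} with Wald 95% CI.
#' @export
logisticOr <- function(outcome, predictor, scalePercent = FALSE,
                       covariates = NULL) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L
       else if (is.logical(outcome)) as.integer(outcome)
       else as.integer(outcome)
  if (length(unique(y[!is.na(y)])) != 2 || !all(y %in% c(0L, 1L), na.rm = TRUE))
    stop("outcome must contain both classes (coded 0/1)")
  x <- if (scalePercent) predictor * 100 else predictor
  d <- data.frame(y = y, x = x)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (length(unique(d$y)) != 2) stop("outcome must contain both classes")
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)$coefficients
  b <- s["x", "Estimate"]; se <- s["x", "Std. Error"]
  if (sepWarn || abs(b) > 50 || se > 1e3)
    stop("complete or quasi-complete separation: odds ratio not identifiable")
  orv <- exp(b)
  ci <- exp(b + c(-1, 1) * qnorm(0.975) * se)
  statResult("binary logistic regression", "logistic",
             c(z = s["x", "z value"]), df = fit$df.residual,
             p = s["x", "Pr(>|z|)"],
             effect = list(OR = orv, ci = ci, coefficient = b,
                           per = if (scalePercent) 0.01 else 1),
             notes = sprintf("dropped %d incomplete rows", sum(!cc)))
}

#' Covariate-adjusted partial correlation
#'
#' Residualizes x and y on the covariates (with intercept) by least squares
#' and reports the Pearson correlation of the residuals, with
#' p from a t-distribution on n - 2 - k degrees of freedom and a Fisher-z
#' 95% CI. With no covariates this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame/matrix of numeric covariates.
#' @return a [StatResult-class]; \code{effect$r} is the partial correlation.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(x))
  covariates <- as.data.frame(covariates)
  cc <- if (ncol(covariates)) complete.cases(x, y, covariates)
        else complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  Z <- cbind(`(Intercept)` = 1, as.matrix(covariates[cc, , drop = FALSE]))
  storage.mode(Z) <- "double"
  k <- ncol(Z) - 1L
  n <- length(x)
  if (n <= k + 2) stop("need n > number of covariates + 2")
  rx <- lm.fit(Z, x)$residuals
  ry <- lm.fit(Z, y)$residuals
  # residuals numerically zero relative to the input scale are "constant"
  # (e.g. x is an exact linear function of the covariates)
  if (sd(rx) <= 1e-10 * max(sd(x), .Machine$double.xmin) ||
      sd(ry) <= 1e-10 * max(sd(y), .Machine$double.xmin))
    stop("constant residuals: partial correlation undefined")
  r <- cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  zse <- 1 / sqrt(n - k - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) * zse)
  statResult("partial correlation", "partial_correlation",
             c(t = tval), df = df, p = min(p, 1),
             effect = list(r = r, ci = ci, n = n, k = k),
             notes = sprintf("dropped %d incomplete rows", sum(!cc)))
}

#' Assumption-gated two-sample comparison
#'
#' Same gate as [omnibusThreeGroup()] but two-sample: pooled-variance t-test
#' when both groups pass Shapiro-Wilk and Levene passes, Mann-Whitney U
#' otherwise.
#'
#' @param values numeric vector.
#' @param groups two-level labels, each n >= 2.
#' @param alpha gate level.
#' @return a [StatResult-class].
#' @export
twoSampleCompare <- function(values, groups, alpha = 0.05) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  gate <- gateAssumptions(values, groups, alpha)
  notes <- sprintf("gate: normal=%s homogeneous=%s",
                   paste(gate$normal, collapse = "/"), gate$homogeneous)
  if (gate$pass) {
    tt <- t.test(values ~ groups, var.equal = TRUE)
    statResult("two-sample comparison", "t_test",
               c(t = unname(tt$statistic)), df = unname(tt$parameter),
               p = tt$p.value,
               effect = list(difference = diff(rev(tt$estimate)),
                             ci = tt$conf.int),
               notes = notes)
  } else {
    wt <- wilcox.test(values ~ groups, exact = FALSE, correct = FALSE)
    statResult("two-sample comparison", "mann_whitney",
               c(W = unname(wt$statistic)), df = NA_real_, p = wt$p.value,
               notes = notes)
  }
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction; df = (r-1)(c-1).
#'
#' @param counts matrix of non-negative integer counts with positive row and
#'   column totals.
#' @return a [StatResult-class].
#' @export
chiSquareCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("every row and column total must be positive")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  statResult("chi-square test of independence", "chi_square",
             c(X2 = unname(ct$statistic)), df = unname(ct$parameter),
             p = ct$p.value)
}
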
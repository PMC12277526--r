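# The full cohort analysis roster and its machine/human-readable reports.

.defaultStatsConfig <- function() {
  list(
    alpha = 0.05,
    scalePercent = TRUE,
    ancovaCovariates = c("duration", "FPG", "LDL"),
    pcorrHippoCovariates = c("gender", "age", "education", "BMI"),
    pcorrCognitiveCovariates = c("gender", "age", "education", "SBP", "DBP",
                                 "FPG", "FINS", "HbA1c", "HOMA_IR", "BMI",
                                 "LDL", "HDL", "TG", "TC"),
    clinicalVars = c("age", "education", "BMI", "SBP", "DBP", "HbA1c", "FPG",
                     "FINS", "HOMA_IR", "LDL", "HDL", "TG", "TC"),
    cognitiveScores = c("MoCA", "AVLT_immediate", "AVLT_5min", "AVLT_delay",
                        "AVLT_recall", "GPT_R", "GPT_L", "DST_forward",
                        "DST_backward", "CDT", "DSST", "TMT_A"))
}

# numeric covariate matrix, with gender coded as a male indicator
.covariateFrame <- function(cohort, vars) {
  out <- lapply(vars, function(v) {
    if (v == "gender") as.numeric(cohort$gender == "male") else cohort[[v]]
  })
  names(out) <- ifelse(vars == "gender", "gender_male", vars)
  as.data.frame(out)
}

omnibusWithPosthoc <- function(values, groups, alpha = 0.05) {
  omni <- omnibusThreeGroup(values, groups, alpha)
  ph <- posthocPairwise(values, groups, omni@route)
  omni@posthoc <- ph@posthoc
  omni
}

#' Analysis keys produced by [runFullStats()]
#' @param config optional configuration list (same as [runFullStats()]).
#' @return character vector of report keys, in output order.
#' @export
fullStatsKeys <- function(config = list()) {
  cfg <- utils::modifyList(.defaultStatsConfig(), config)
  idx <- c("left", "right", "mean")
  metrics <- c("fa", "md", "ad", "rd")
  sides <- c("left", "right")
  c(paste0("table1_", c("gender", "duration", cfg$clinicalVars,
                        cfg$cognitiveScores)),
    paste0("alps_omnibus_", idx),
    paste0("alps_variants_", c("HC", "DMNC", "DMMCI")),
    paste0("ancova_dm_", idx),
    paste0("logistic_mci_", idx),
    as.vector(t(outer(metrics, sides, function(m, s)
      paste0("hippo_t2dm_vs_hc_", m, "_", s)))),
    as.vector(t(outer(idx, paste0(rep(metrics, each = 2), "_", sides),
                      function(i, ms) paste0("pcorr_t2dm_", i, "_", ms)))),
    as.vector(t(outer(idx, paste0(rep(metrics, each = 2), "_", sides),
                      function(i, ms) paste0("pcorr_hc_", i, "_", ms)))),
    as.vector(t(outer(idx, cfg$cognitiveScores, function(i, s)
      paste0("pcorr_all_", i, "_", s)))))
}

#' Run the complete cohort statistics chain
#'
#' Runs the complete cohort analysis roster on a cohort table: group
#' comparisons of every clinical and cognitive column (chi-square for gender,
#' two-group Kruskal-Wallis for disease duration, gated omnibus + BH-adjusted
#' post hoc otherwise); gated omnibus + post hoc for the three ALPS-indices;
#' the within-group comparison of the three ALPS variants; the
#' DMNC-vs-DMMCI covariate-adjusted linear model (duration, FPG, LDL); binary
#' logistic models for MCI status within the diabetic groups (percent-form
#' ALPS); two-sample comparisons of hippocampal metrics between diabetic and
#' control participants; and covariate-adjusted partial correlations of ALPS
#' with hippocampal metrics (within the diabetic and control groups) and with
#' cognitive scores (all participants).
#'
#' @param cohort data.frame with one row per subject: \code{group}
#'   (HC/DMNC/DMMCI), the measured columns \code{alps_left/right/mean} and
#'   \code{hippo_<metric>_<side>}, plus the clinical/cognitive columns.
#' @param config optional list overriding \code{.defaultStatsConfig()} fields
#'   (covariate lists, score roster, alpha, scalePercent).
#' @return named list of [StatResult-class] objects; names are
#'   [fullStatsKeys()].
#' @export
runFullStats <- function(cohort, config = list()) {
  cfg <- utils::modifyList(.defaultStatsConfig(), config)
  idx <- c("left", "right", "mean")
  metrics <- c("fa", "md", "ad", "rd")
  sides <- c("left", "right")
  need <- c("group", "gender", "duration", cfg$clinicalVars,
            cfg$cognitiveScores, paste0("alps_", idx),
            paste0("hippo_", rep(metrics, each = 2), "_", sides))
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort lacks required columns: ", paste(missing, collapse = ", "))
  g <- factor(cohort$group, levels = c("HC", "DMNC", "DMMCI"))
  if (sum(table(g) > 0) < 2) stop("at least two non-empty groups are required")
  dm <- g %in% c("DMNC", "DMMCI")
  res <- list()

  # --- demographic / clinical / cognitive group comparisons ---------------
  res$table1_gender <- chiSquareCounts(table(cohort$gender, g))
  durDm <- cohort$duration[dm]
  kt <- kruskal.test(durDm, factor(as.character(g[dm])))
  res$table1_duration <- statResult(
    "disease duration (diabetic groups)", "kruskal_wallis",
    c(H = unname(kt$statistic)), df = unname(kt$parameter), p = kt$p.value)
  for (v in c(cfg$clinicalVars, cfg$cognitiveScores))
    res[[paste0("table1_", v)]] <- omnibusWithPosthoc(cohort[[v]], g, cfg$alpha)

  # --- ALPS-index group structure -----------------------------------------
  for (i in idx)
    res[[paste0("alps_omnibus_", i)]] <-
      omnibusWithPosthoc(cohort[[paste0("alps_", i)]], g, cfg$alpha)
  for (grp in levels(g)) {
    sel <- g == grp
    stacked <- unlist(cohort[sel, paste0("alps_", idx)])
    lab <- rep(c("ALPS_L", "ALPS_R", "ALPS"), each = sum(sel))
    res[[paste0("alps_variants_", grp)]] <-
      omnibusWithPosthoc(stacked, lab, cfg$alpha)
  }

  # --- DMNC vs DMMCI adjusted comparison and MCI logistic models ----------
  for (i in idx) {
    res[[paste0("ancova_dm_", i)]] <- ancovaGroupEffect(
      cohort[[paste0("alps_", i)]][dm],
      droplevels(g[dm]),
      .covariateFrame(cohort[dm, ], cfg$ancovaCovariates))
    res[[paste0("logistic_mci_", i)]] <- logisticOr(
      as.integer(g[dm] == "DMMCI"),
      cohort[[paste0("alps_", i)]][dm],
      scalePercent = cfg$scalePercent)
  }

  # --- hippocampal metrics: diabetic vs control ---------------------------
  t2dmLab <- ifelse(dm, "T2DM", "HC")
  for (m in metrics) for (s in sides)
    res[[paste0("hippo_t2dm_vs_hc_", m, "_", s)]] <-
      twoSampleCompare(cohort[[paste0("hippo_", m, "_", s)]], t2dmLab,
                       cfg$alpha)

  # --- partial correlations ------------------------------------------------
  hipCov <- .covariateFrame(cohort, cfg$pcorrHippoCovariates)
  for (i in idx) for (m in metrics) for (s in sides) {
    col <- paste0("hippo_", m, "_", s)
    res[[paste0("pcorr_t2dm_", i, "_", m, "_", s)]] <- partialCorrelation(
      cohort[[paste0("alps_", i)]][dm], cohort[[col]][dm],
      hipCov[dm, , drop = FALSE])
    res[[paste0("pcorr_hc_", i, "_", m, "_", s)]] <- partialCorrelation(
      cohort[[paste0("alps_", i)]][!dm], cohort[[col]][!dm],
      hipCov[!dm, , drop = FALSE])
  }
  cogCov <- .covariateFrame(cohort, cfg$pcorrCognitiveCovariates)
  for (i in idx) for (sc in cfg$cognitiveScores)
    res[[paste0("pcorr_all_", i, "_", sc)]] <- partialCorrelation(
      cohort[[paste0("alps_", i)]], cohort[[sc]], cogCov)

  res[fullStatsKeys(config)]
}

# mean +/- SD when the normality/homogeneity gate passes, median (IQR)
# otherwise — the standard clinical reporting convention.
describeByGroup <- function(values, groups, alpha = 0.05) {
  keep <- is.finite(values) & !is.na(groups)
  gate <- tryCatch(gateAssumptions(values[keep], groups[keep], alpha)$pass,
                   error = function(e) FALSE)
  vapply(split(values[keep], groups[keep]), function(v) {
    if (gate) sprintf("%.2f ± %.2f", mean(v), sd(v))
    else sprintf("%.2f (%.2f, %.2f)", median(v), quantile(v, 0.25),
                 quantile(v, 0.75))
  }, character(1))
}

statResultToList <- function(x) {
  list(test = x@test, route = x@route,
       statistic = as.list(x@statistic), df = x@df, p = x@p,
       posthoc = if (nrow(x@posthoc)) x@posthoc else NULL,
       effect = x@effect, notes = x@notes)
}

#' Write a stats report as JSON
#' @param report named list of StatResults from [runFullStats()].
#' @param path output file.
#' @export
statsReportJson <- function(report, path) {
  jsonlite::write_json(lapply(report, statResultToList), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write a human-readable Markdown stats report
#'
#' Emits group-descriptive tables in the conventional clinical-summary layout
#' plus a per-analysis listing of test, route, statistic and p-values.
#'
#' @param report named list of StatResults.
#' @param cohort the cohort table the report was computed from.
#' @param path output file.
#' @export
statsReportMarkdown <- function(report, cohort, path) {
  g <- factor(cohort$group, levels = c("HC", "DMNC", "DMMCI"))
  lines <- c("# Cohort analysis report", "",
             sprintf("Subjects: %d (%s)", nrow(cohort),
                     paste(sprintf("%s n=%d", levels(g), table(g)),
                           collapse = ", ")), "")
  lines <- c(lines, "## Group descriptives", "",
             "| Variable | HC | DMNC | DMMCI | Statistic | p |",
             "|---|---|---|---|---|---|")
  for (key in grep("^table1_", names(report), value = TRUE)) {
    v <- sub("^table1_", "", key)
    r <- report[[key]]
    desc <- if (v %in% names(cohort) && is.numeric(cohort[[v]]))
      describeByGroup(cohort[[v]], g) else c("-", "-", "-")
    if (v == "duration") desc["HC"] <- "NA"
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s = %.3f | %.3g |", v,
      desc["HC"], desc["DMNC"], desc["DMMCI"],
      names(r@statistic)[1], r@statistic[1], r@p[1]))
  }
  lines <- c(lines, "", "## ALPS-index comparisons", "",
             "| Analysis | Route | Statistic | p | Post hoc (BH) |",
             "|---|---|---|---|---|")
  for (key in grep("^(alps_|ancova_|logistic_)", names(report), value = TRUE)) {
    r <- report[[key]]
    ph <- if (nrow(r@posthoc))
      paste(sprintf("%s p=%.3g", r@posthoc$comparison, r@posthoc$p_adj),
            collapse = "; ") else ""
    lines <- c(lines, sprintf("| %s | %s | %s = %.3f | %.3g | %s |", key,
                              r@route, names(r@statistic)[1], r@statistic[1],
                              r@p[1], ph))
  }
  lines <- c(lines, "", "## Hippocampal and correlation analyses", "",
             "| Analysis | Route | Statistic | p | Effect |",
             "|---|---|---|---|---|")
  for (key in grep("^(hippo_|pcorr_)", names(report), value = TRUE)) {
    r <- report[[key]]
    eff <- if (!is.null(r@effect$r)) sprintf("r = %.3f", r@effect$r)
    else if (!is.null(r@effect$difference))
      sprintf("diff = %.4g", r@effect$difference) else ""
    lines <- c(lines, sprintf("| %s | %s | %s = %.3f | %.3g | %s |", key,
                              r@route, names(r@statistic)[1], r@statistic[1],
                              r@p[1], eff))
  }
  writeLines(lines, path)
  invisible(path)
}
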
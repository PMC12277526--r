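# Group presets: population parameters for the three study groups (healthy
# controls, diabetic with normal cognition, diabetic with mild cognitive
# impairment). ALPS locations/spreads are calibrated so that the *pipeline-
# recovered* cohort statistics match the reported group values; the
# calibration search lives in scripts/calibrate_presets.R and its frozen
# output is the .alpsCalibration table below.

# Per-side ALPS location (mean or median, per locType), lognormal sigma of
# the biological subject-to-subject jitter, and location recovery calibration
# calL/calR (the magnitude-MRI noise floor deflates the pipeline-recovered
# index by a nearly constant relative factor at SNR 20, so the ground-truth
# location is the reported value divided by that factor). All four numbers
# per group were solved by scripts/calibrate_presets.R at seed 0 and are
# frozen here.
.alpsCalibration <- list(
  HC    = list(locType = "mean",   locL = 1.76, sigL = 0.14689, calL = 1.00010,
               locR = 1.59, sigR = 0.13147, calR = 0.99989),
  DMNC  = list(locType = "mean",   locL = 1.80, sigL = 0.13818, calL = 1.00010,
               locR = 1.58, sigR = 0.13854, calR = 0.99989),
  DMMCI = list(locType = "median", locL = 1.71, sigL = 0.12305, calL = 1.00009,
               locR = 1.48, sigR = 0.16872, calR = 0.99991)
)

# Covariate population distributions per group, transcribed from the cohort's
# demographic/clinical/cognitive summary table. Symmetric-looking scores use a
# normal matched to the median/IQR ("qnormal"), right-skewed laboratory values
# and timed tests a lognormal matched to median/IQR, and rows reported as
# mean +/- SD a plain normal. Gender is Bernoulli with the group male
# fraction.
.covariateTable <- function(label) {
  qn <- function(med, q1, q3) list(type = "qnormal", med = med, q1 = q1, q3 = q3)
  ln <- function(med, q1, q3) list(type = "lognormal", med = med, q1 = q1, q3 = q3)
  no <- function(mean, sd) list(type = "normal", mean = mean, sd = sd)
  tab <- switch(label,
    HC = list(
      gender = list(type = "binary", p = 11 / 37),
      age = qn(51, 45, 59), education = qn(10, 8, 15),
      duration = list(type = "none"),
      BMI = qn(22.94, 21.3, 24.12),
      SBP = no(124.22, 12.96), DBP = no(82.59, 8.95),
      HbA1c = ln(5.7, 5.5, 5.9), FPG = ln(5.14, 4.8, 5.51),
      FINS = ln(7.65, 5.74, 10.4), HOMA_IR = ln(1.72, 1.41, 2.36),
      LDL = ln(3.05, 2.72, 3.31), HDL = ln(1.47, 1.2, 1.84),
      TG = ln(1.28, 0.89, 1.58), TC = ln(4.92, 4.6, 5.58),
      MoCA = qn(28, 27, 28),
      AVLT_immediate = no(22.78, 4.45), AVLT_5min = no(8.62, 1.53),
      AVLT_delay = qn(9, 8, 10), AVLT_recall = qn(12, 11, 12),
      GPT_R = ln(62, 55, 69), GPT_L = ln(67, 60, 75),
      DST_forward = qn(8, 7, 9), DST_backward = qn(4, 3, 5),
      CDT = qn(4, 3, 4), DSST = qn(45, 36, 54), TMT_A = ln(42, 31, 54)),
    DMNC = list(
      gender = list(type = "binary", p = 15 / 37),
      age = qn(49, 45, 55), education = qn(12, 9, 15),
      duration = ln(4, 2, 12),
      BMI = qn(23.73, 22.04, 25.62),
      SBP = no(120.38, 14.08), DBP = no(81.81, 9.13),
      HbA1c = ln(7.7, 6.5, 9.1), FPG = ln(6.73, 3.74, 10.79),
      FINS = ln(7.7, 6.5, 9.1), HOMA_IR = ln(2.28, 1.39, 3.78),
      LDL = ln(3.39, 2.92, 3.79), HDL = ln(1.12, 0.99, 1.43),
      TG = ln(1.41, 1.03, 2.35), TC = ln(5.12, 4.55, 5.41),
      MoCA = qn(27, 27, 28),
      AVLT_immediate = no(21.68, 4.36), AVLT_5min = no(8.32, 1.8),
      AVLT_delay = qn(8, 7, 9), AVLT_recall = qn(12, 11, 12),
      GPT_R = ln(72, 64, 88), GPT_L = ln(77, 69, 89),
      DST_forward = qn(8, 6, 9), DST_backward = qn(5, 4, 5),
      CDT = qn(4, 4, 4), DSST = qn(39, 30, 50), TMT_A = ln(43, 37, 47)),
    DMMCI = list(
      gender = list(type = "binary", p = 19 / 39),
      age = qn(53, 48.5, 59), education = qn(9, 8, 12),
      duration = ln(4, 2, 8.5),
      BMI = qn(23.39, 20.79, 26.01),
      SBP = no(127.26, 15.75), DBP = no(82.1, 8.74),
      HbA1c = ln(7.4, 6.4, 9.15), FPG = ln(6.6, 6, 7.84),
      FINS = ln(6.94, 4.745, 12.03), HOMA_IR = ln(2.21, 1.45, 4.41),
      LDL = ln(2.9, 2.285, 3.4), HDL = ln(1.14, 0.94, 1.45),
      TG = ln(1.45, 1.095, 2.14), TC = ln(4.74, 3.745, 5.42),
      MoCA = qn(23, 21, 25),
      AVLT_immediate = no(18.97, 4.11), AVLT_5min = no(6.56, 2.07),
      AVLT_delay = qn(6, 5, 7.5), AVLT_recall = qn(11, 10, 12),
      GPT_R = ln(83, 69, 98.5), GPT_L = ln(87, 78, 113),
      DST_forward = qn(8, 6, 8), DST_backward = qn(4, 3, 5),
      CDT = qn(4, 3, 4), DSST = qn(32, 26.5, 41.5), TMT_A = ln(48, 41.5, 68)),
    stop("unknown group label: ", label))
  tab
}

#' Group preset: population parameters for one study group
#'
#' Bundles the calibrated ALPS-determining diffusivity distributions, the
#' hippocampal FA/MD population values and the covariate distributions for a
#' group. Subject-to-subject ALPS variation is a lognormal with shared
#' left/right component (correlation \code{rho}); the underlying perivascular
#' diffusivities are scaled so the ground-truth per-side ALPS-index equals the
#' drawn value exactly.
#'
#' @param label one of "HC", "DMNC", "DMMCI".
#' @return a list of class \code{GroupPreset}.
#' @export
groupPreset <- function(label = c("HC", "DMNC", "DMMCI")) {
  label <- match.arg(label)
  cal <- .alpsCalibration[[label]]
  preset <- list(
    label = label,
    alps = c(cal, list(rho = 0.5, dPerp = 0.6e-3, dFiber = 1.5e-3,
                       baseSigma = 0.05)),
    # the study found no group difference in whole-hippocampus diffusion
    # metrics, so the population values are shared across groups
    hippo = list(faMean = 0.17, faSd = 0.015, mdMean = 8.8e-4, mdSd = 4e-5),
    covariates = .covariateTable(label))
  stopifnot(preset$alps$sigL >= 0, preset$alps$sigR >= 0,
            preset$covariates$gender$p >= 0, preset$covariates$gender$p <= 1)
  class(preset) <- "GroupPreset"
  preset
}

#' All three study-group presets
#' @return named list of GroupPresets (HC, DMNC, DMMCI)
#' @export
studyPresets <- function() {
  setNames(lapply(c("HC", "DMNC", "DMMCI"), groupPreset),
           c("HC", "DMNC", "DMMCI"))
}

#' The published group sizes
#' @return named integer vector c(HC = 37, DMNC = 37, DMMCI = 39)
#' @export
studySizes <- function() c(HC = 37L, DMNC = 37L, DMMCI = 39L)

# Draw an n-row covariate table from a preset. Integer-valued cognitive
# scores are rounded and clamped to their instrument ranges; MoCA respects
# the groups' inclusion windows (>= 26 for cognitively normal groups,
# 17..25 for the impaired group). qnormal spreads get a small floor so a
# degenerate printed IQR (e.g. 4(4,4)) still yields a non-constant column.
drawCovariates <- function(preset, n, seed) {
  tab <- preset$covariates
  withSeed(seed, {
    out <- list()
    for (nm in names(tab)) {
      d <- tab[[nm]]
      out[[nm]] <- switch(d$type,
        none = rep(NA_real_, n),
        binary = ifelse(rbinom(n, 1, d$p) == 1, "male", "female"),
        normal = rnorm(n, d$mean, d$sd),
        qnormal = rnorm(n, d$med, max((d$q3 - d$q1) / 1.3489795, 0.25)),
        lognormal = rlnorm(n, log(d$med), (log(d$q3) - log(d$q1)) / 1.3489795),
        stop("unknown covariate type"))
    }
    out$age <- round(pmin(pmax(out$age, 30), 70))
    out$education <- round(pmax(out$education, 6))
    mocaLim <- if (preset$label == "DMMCI") c(17, 25) else c(26, 30)
    out$MoCA <- round(pmin(pmax(out$MoCA, mocaLim[1]), mocaLim[2]))
    for (nm in c("AVLT_delay", "AVLT_recall", "DST_forward", "DST_backward",
                 "DSST"))
      out[[nm]] <- round(pmax(out[[nm]], 0))
    out$CDT <- round(pmin(pmax(out$CDT, 0), 4))
    as.data.frame(out, stringsAsFactors = FALSE)
  })
}
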
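# End-to-end orchestration: phantom -> tensor fit -> ALPS -> hippocampus ->
# cohort statistics, as one reproducible run.

#' Per-subject analysis: maps, ALPS-indices and hippocampal metrics
#'
#' Runs shell selection, WLLS tensor fitting, eigen-decomposition, ALPS ROI
#' extraction and hippocampal label aggregation on one dataset.
#'
#' @param dwi a [DWIDataset-class].
#' @param rois ALPS ROI table (see [defaultRois()]).
#' @param atlas a [LabelVolume-class] with the bilateral hippocampal labels.
#' @param bMax shell cutoff passed to [selectShells()].
#' @param inclusive include the cutoff shell ([selectShells()]).
#' @param regionIds hippocampal label IDs (left, right).
#' @return one-row data.frame: alps_left/right/mean, the eight ROI means,
#'   hippo_<metric>_<side>.
#' @export
analyzeSubject <- function(dwi, rois, atlas, bMax = 1000, inclusive = FALSE,
                           regionIds = c(37L, 38L)) {
  low <- selectShells(dwi, bMax = bMax, inclusive = inclusive)
  maps <- eigenMaps(fitTensor(low))
  alps <- computeAlps(maps, rois)
  hip <- aggregateRegionMetrics(maps, atlas, regionIds)
  row <- data.frame(alps_left = alps@left, alps_right = alps@right,
                    alps_mean = alps@mean)
  for (nm in names(alps@roiMeans)) row[[tolower(nm)]] <- alps@roiMeans[[nm]]
  sideOf <- setNames(c("left", "right"), as.character(regionIds))
  for (j in seq_len(nrow(hip)))
    for (m in c("fa", "md", "ad", "rd"))
      row[[paste0("hippo_", m, "_", sideOf[[as.character(hip$id[j])]])]] <-
        hip[[m]][j]
  row
}

#' Assemble a run configuration
#'
#' @param mode "synthetic" (default) or "real".
#' @param outputDir directory for all artifacts.
#' @param seed cohort seed (mandatory in synthetic mode).
#' @param sizes named group sizes (synthetic mode).
#' @param snr phantom SNR (synthetic mode).
#' @param grid "reduced" (64x64x32 test grid), "template" (182x218x182) or
#'   "smoke" (32x32x16 smoke-profile grid).
#' @param nDirections gradient directions per shell.
#' @param shells b-value list for the acquisition scheme.
#' @param bMax,inclusive shell-selection rule for fitting.
#' @param oneBased interpret ROI coordinates as 1-based (real mode).
#' @param dwiPath,bvalsPath,bvecsPath,maskPath,atlasPath,roisPath input files
#'   (real mode; roisPath optionally overrides the default ROIs in either
#'   mode).
#' @param stats list of overrides for the statistics configuration.
#' @return validated list of class \code{RunConfig}.
#' @export
runConfig <- function(mode = c("synthetic", "real"), outputDir, seed = NULL,
                      sizes = studySizes(), snr = 20, grid = "reduced",
                      nDirections = 99L,
                      shells = c(0, 300, 350, 650, 950, 1000, 1350, 1650,
                                 1700, 2000, 2700, 3000),
                      bMax = 1000, inclusive = FALSE, oneBased = FALSE,
                      dwiPath = NULL, bvalsPath = NULL, bvecsPath = NULL,
                      maskPath = NULL, atlasPath = NULL, roisPath = NULL,
                      stats = list()) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(seed))
    stop("synthetic mode requires a seed")
  sizes <- unlist(sizes)
  if (is.null(names(sizes)) && length(sizes) <= 3)
    names(sizes) <- c("HC", "DMNC", "DMMCI")[seq_along(sizes)]
  shells <- unlist(shells)
  if (mode == "real") {
    for (p in c(dwiPath, bvalsPath, bvecsPath))
      if (is.null(p) || !file.exists(p))
        stop("real mode requires existing dwi/bvals/bvecs paths")
  }
  cfg <- list(mode = mode, outputDir = outputDir, seed = seed, sizes = sizes,
              snr = snr, grid = grid, nDirections = nDirections,
              shells = shells, bMax = bMax, inclusive = inclusive,
              oneBased = oneBased, dwiPath = dwiPath, bvalsPath = bvalsPath,
              bvecsPath = bvecsPath, maskPath = maskPath,
              atlasPath = atlasPath, roisPath = roisPath, stats = stats)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file whose fields mirror [runConfig()] arguments.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

#' Run the full pipeline
#'
#' Synthetic mode generates the cohort phantoms subject by subject (constant
#' memory), analyses each through shell selection, tensor fitting, ALPS ROI
#' extraction and hippocampal aggregation, then runs the complete statistics
#' chain; real mode analyses one supplied DWI dataset. Artifacts: the cohort
#' CSV, a JSON and a Markdown statistics report, and a YAML provenance file
#' (config echo, seeds, package version). Outputs are identical for identical
#' configurations.
#'
#' @param config a \code{RunConfig} from [runConfig()] or [readRunConfig()].
#' @param verbose print per-stage progress.
#' @return invisibly, a list with the cohort table, the stats report (synthetic
#'   mode) and the artifact paths.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  paths <- list()
  if (config$mode == "synthetic") {
    spec <- switch(config$grid,
                   template = templatePhantomSpec(snr = config$snr),
                   smoke = smokePhantomSpec(snr = config$snr),
                   reducedPhantomSpec(snr = config$snr))
    rois <- if (!is.null(config$roisPath)) readRoisJson(config$roisPath)
            else spec$rois
    scheme <- makeScheme(config$shells, config$nDirections,
                         seed = deriveSeed(config$seed, "scheme"))
    atlas <- syntheticHippocampusAtlas(spec)
    presets <- studyPresets()[names(config$sizes)]
    say("stage simulate+fit: %d subjects on %s grid",
        sum(config$sizes), config$grid)
    coh <- generateCohort(presets, config$sizes, spec, scheme,
                          seed = config$seed, keepImaging = FALSE,
                          analyze = function(ph)
                            analyzeSubject(ph$dwi, rois, atlas,
                                           bMax = config$bMax,
                                           inclusive = config$inclusive))
    cohort <- coh$covariates
    paths$cohort <- file.path(config$outputDir, "cohort.csv")
    writeCohortCsv(cohort, paths$cohort)
    say("stage stats: %d analyses", length(fullStatsKeys(config$stats)))
    report <- runFullStats(cohort, config$stats)
    paths$statsJson <- file.path(config$outputDir, "stats.json")
    statsReportJson(report, paths$statsJson)
    paths$statsMd <- file.path(config$outputDir, "stats.md")
    statsReportMarkdown(report, cohort, paths$statsMd)
  } else {
    say("stage read: %s", config$dwiPath)
    dwi <- readDwi(config$dwiPath, config$bvalsPath, config$bvecsPath,
                   config$maskPath)
    rois <- if (!is.null(config$roisPath)) readRoisJson(config$roisPath)
            else defaultRois(oneBased = config$oneBased)
    if (is.null(config$atlasPath))
      stop("real mode requires an atlas label volume (atlasPath)")
    atlas <- readLabelVolume(config$atlasPath)
    say("stage fit+extract")
    cohort <- analyzeSubject(dwi, rois, atlas, bMax = config$bMax,
                             inclusive = config$inclusive)
    report <- NULL
    paths$cohort <- file.path(config$outputDir, "metrics.csv")
    writeCohortCsv(cohort, paths$cohort)
  }
  prov <- config
  class(prov) <- NULL
  prov$package_version <- as.character(utils::packageVersion("alpsdti"))
  prov$stats <- NULL
  paths$provenance <- file.path(config$outputDir, "provenance.yaml")
  yaml::write_yaml(prov[!vapply(prov, is.null, logical(1))], paths$provenance)
  say("done: %s", config$outputDir)
  invisible(list(cohort = cohort, report = report, paths = paths))
}
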
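#' @import methods
#' @importFrom stats rnorm rbinom rlnorm runif median sd var cor quantile
#'   aov kruskal.test shapiro.test TukeyHSD chisq.test t.test wilcox.test
#'   lm glm binomial coef vcov p.adjust pt pf pchisq pnorm qnorm complete.cases
#'   setNames anova lm.fit
NULL

#' AcquisitionScheme: a diffusion-MRI measurement set
#'
#' One row per acquired volume: a b-value (s/mm^2) and a unit gradient
#' direction. b = 0 entries carry a zero direction vector.
#'
#' @slot bvals numeric vector of non-negative b-values (s/mm^2).
#' @slot bvecs numeric matrix, one row per measurement, three columns; rows
#'   with b > 0 have Euclidean norm 1.
#' @exportClass AcquisitionScheme
setClass("AcquisitionScheme",
  representation(bvals = "numeric", bvecs = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@bvecs) != length(object@bvals))
      msg <- c(msg, "bvecs must have one row per b-value")
    if (ncol(object@bvecs) != 3L)
      msg <- c(msg, "bvecs must have three columns")
    if (any(object@bvals < 0))
      msg <- c(msg, "b-values must be non-negative")
    if (!any(object@bvals == 0))
      msg <- c(msg, "scheme must contain at least one b = 0 measurement")
    dwi <- object@bvals > 0
    if (any(dwi)) {
      nrm <- sqrt(rowSums(object@bvecs[dwi, , drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-9))
        msg <- c(msg, "directions with b > 0 must have unit norm (tol 1e-9)")
    }
    if (length(msg)) msg else TRUE
  })

#' DWIDataset: a masked 4-D diffusion-weighted signal
#'
#' Signals are stored compactly as an (in-mask voxel) x (measurement) matrix
#' together with the grid dimensions and the logical mask; \code{as4D()}
#' expands to the full 4-D array when needed (e.g. for NIfTI export).
#'
#' @slot signal numeric matrix, rows = voxels where \code{mask} is TRUE (in
#'   array order), columns = measurements; arbitrary units, non-negative.
#' @slot mask logical 3-D array marking voxels carrying signal.
#' @slot scheme an \code{AcquisitionScheme} with one entry per signal column.
#' @slot voxelSize isotropic voxel edge length in mm.
#' @exportClass DWIDataset
setClass("DWIDataset",
  representation(signal = "matrix", mask = "array", scheme = "AcquisitionScheme",
                 voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@mask)) != 3L)
      msg <- c(msg, "mask must be a 3-D logical array")
    if (!is.logical(object@mask))
      msg <- c(msg, "mask must be logical")
    if (nrow(object@signal) != sum(object@mask))
      msg <- c(msg, "signal must have one row per in-mask voxel")
    if (ncol(object@signal) != length(object@scheme@bvals))
      msg <- c(msg, "signal must have one column per scheme measurement")
    if (any(!is.finite(object@signal)) || any(object@signal < 0))
      msg <- c(msg, "signals must be finite and non-negative")
    if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
      msg <- c(msg, "voxelSize must be a single positive number (mm)")
    if (length(msg)) msg else TRUE
  })

#' TensorField: voxelwise symmetric diffusion tensors
#'
#' @slot D numeric matrix with one row per grid voxel (array order) and six
#'   columns \code{Dxx, Dyy, Dzz, Dxy, Dxz, Dyz} in mm^2/s; rows outside the
#'   mask are zero.
#' @slot mask logical 3-D array of fitted voxels.
#' @slot flags logical vector, one per grid voxel; TRUE marks voxels excluded
#'   from the fit (e.g. non-positive signals).
#' @slot residualNorm numeric vector of per-voxel log-domain residual norms.
#' @slot voxelSize voxel edge length in mm.
#' @exportClass TensorField
setClass("TensorField",
  representation(D = "matrix", mask = "array", flags = "logical",
                 residualNorm = "numeric", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    nv <- prod(dim(object@mask))
    if (nrow(object@D) != nv) msg <- c(msg, "D must have one row per grid voxel")
    if (ncol(object@D) != 6L) msg <- c(msg, "D must have six columns")
    if (length(object@flags) != nv) msg <- c(msg, "flags length must equal voxel count")
    inmask <- as.vector(object@mask) & !object@flags
    if (any(!is.finite(object@D[inmask, ])))
      msg <- c(msg, "tensors must be finite inside the mask")
    if (length(msg)) msg else TRUE
  })

#' DiffusivityMaps: scalar maps derived from a tensor field
#'
#' Holds the tensor diagonal (dxx, dyy, dzz), sorted eigenvalues and the
#' standard rotation-invariant metrics. FA is in [0, 1]; diffusivities are in
#' mm^2/s. Voxels with clamped negative eigenvalues or excluded fits are
#' flagged.
#'
#' @slot dxx,dyy,dzz,fa,md,ad,rd numeric 3-D arrays.
#' @slot evals numeric matrix (voxel x 3), eigenvalues sorted descending.
#' @slot flags logical vector per voxel (degenerate or excluded voxels).
#' @slot mask logical 3-D array.
#' @slot voxelSize voxel edge length in mm.
#' @exportClass DiffusivityMaps
setClass("DiffusivityMaps",
  representation(dxx = "array", dyy = "array", dzz = "array",
                 fa = "array", md = "array", ad = "array", rd = "array",
                 evals = "matrix", flags = "logical", mask = "array",
                 voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    dm <- dim(object@mask)
    for (nm in c("dxx", "dyy", "dzz", "fa", "md", "ad", "rd"))
      if (!identical(dim(slot(object, nm)), dm))
        msg <- c(msg, sprintf("map %s must match the mask grid", nm))
    inmask <- as.vector(object@mask) & !object@flags
    fa <- as.vector(object@fa)[inmask]
    if (length(fa) && (any(fa < -1e-12) || any(fa > 1 + 1e-12)))
      msg <- c(msg, "FA must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' LabelVolume: an integer atlas in the map grid
#'
#' @slot labels integer 3-D array of region IDs (0 = background).
#' @slot dictionary named character vector mapping ID (as name) to region name;
#'   must cover every non-zero ID present.
#' @slot voxelSize voxel edge length in mm.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", dictionary = "character", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3-D array")
    ids <- sort(unique(as.vector(object@labels)))
    ids <- ids[ids != 0]
    if (any(ids < 0)) msg <- c(msg, "label IDs must be non-negative")
    missing <- setdiff(as.character(ids), names(object@dictionary))
    if (length(missing))
      msg <- c(msg, paste("dictionary lacks IDs:", paste(missing, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' ALPSResult: ROI diffusivities and the three ALPS-indices
#'
#' The ALPS-index per hemisphere is
#' mean(Dxproj, Dxassoc) / mean(Dyproj, Dzassoc), and the average index is the
#' mean of the two sides.
#'
#' @slot roiMeans named numeric vector of the eight ROI mean diffusivities
#'   (mm^2/s): Dxproj, Dxassoc, Dyproj, Dzassoc for each side (suffix _L/_R).
#' @slot left,right,mean the three dimensionless indices.
#' @exportClass ALPSResult
setClass("ALPSResult",
  representation(roiMeans = "numeric", left = "numeric", right = "numeric",
                 mean = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- as.vector(outer(c("Dxproj", "Dxassoc", "Dyproj", "Dzassoc"),
                            c("_L", "_R"), paste0))
    if (!all(need %in% names(object@roiMeans)))
      msg <- c(msg, "roiMeans must contain the eight named ROI diffusivities")
    if (abs(object@mean - (object@left + object@right) / 2) > 1e-12)
      msg <- c(msg, "mean index must equal (left + right)/2")
    if (length(msg)) msg else TRUE
  })

#' StatResult: a uniform record of one statistical analysis
#'
#' @slot test human-readable analysis name.
#' @slot route the procedure actually taken after assumption gating: one of
#'   anova, kruskal_wallis, t_test, mann_whitney, chi_square, glm, logistic,
#'   partial_correlation.
#' @slot statistic named test statistic (F, H, t, W, X2, ...).
#' @slot df degrees of freedom (possibly length 2).
#' @slot p raw p-value of the omnibus / primary test.
#' @slot posthoc data.frame of pairwise comparisons with raw and BH-adjusted
#'   p-values (zero rows when not applicable).
#' @slot effect list of effect estimates (coefficient, OR, r, ...) with 95% CIs.
#' @slot notes character vector of gating/bookkeeping messages.
#' @exportClass StatResult
setClass("StatResult",
  representation(test = "character", route = "character", statistic = "numeric",
                 df = "numeric", p = "numeric", posthoc = "data.frame",
                 effect = "list", notes = "character"),
  validity = function(object) {
    msg <- character()
    routes <- c("anova", "kruskal_wallis", "t_test", "mann_whitney",
                "chi_square", "glm", "logistic", "partial_correlation")
    if (!object@route %in% routes)
      msg <- c(msg, paste("route must be one of:", paste(routes, collapse = ", ")))
    if (length(object@p) && (any(object@p < 0) || any(object@p > 1)))
      msg <- c(msg, "p must lie in [0, 1]")
    if (nrow(object@posthoc) &&
        all(c("p_raw", "p_adj") %in% names(object@posthoc)) &&
        any(object@posthoc$p_adj + 1e-12 < object@posthoc$p_raw))
      msg <- c(msg, "adjusted p-values must be >= raw p-values")
    if (length(msg)) msg else TRUE
  })
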
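# Template-space DWI phantoms with known ground-truth perivascular
# diffusivities and Rician measurement noise.

#' Forward signal model for one diffusion tensor
#'
#' Stejskal-Tanner monoexponential model S = s0 * exp(-b g' D g), evaluated
#' for every measurement of a scheme.
#'
#' @param tensor symmetric positive-semidefinite 3x3 matrix (mm^2/s).
#' @param scheme an [AcquisitionScheme-class].
#' @param s0 non-diffusion-weighted signal amplitude.
#' @return numeric vector of non-negative signals, one per measurement;
#'   b = 0 entries equal \code{s0} exactly.
#' @export
simulateSignal <- function(tensor, scheme, s0 = 1) {
  stopifnot(is(scheme, "AcquisitionScheme"))
  tensor <- as.matrix(tensor)
  if (!isTRUE(all.equal(tensor, t(tensor), tolerance = 1e-12)))
    stop("tensor must be symmetric")
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-15 * max(abs(ev), 1e-30))
    stop("tensor must be positive semidefinite")
  if (any(scheme@bvals < 0)) stop("negative b-values are not allowed")
  g <- scheme@bvecs
  quad <- rowSums((g %*% tensor) * g)
  s <- s0 * exp(-scheme@bvals * quad)
  s[scheme@bvals == 0] <- s0
  s
}

#' Add Rician noise to magnitude signals
#'
#' Magnitude-MRI noise model: each value S is replaced by
#' |S + n1 + i n2| with n1, n2 ~ Normal(0, sigma^2). With sigma = 0 the
#' input is returned unchanged.
#'
#' @param signal numeric vector or matrix of noise-free magnitudes.
#' @param sigma Gaussian channel standard deviation (same units as signal).
#' @param seed integer seed; the same seed always yields the same noise.
#' @return object of the same shape as \code{signal}, non-negative.
#' @export
addRicianNoise <- function(signal, sigma, seed = 0L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signal)
  withSeed(seed, {
    n <- length(signal)
    out <- sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
    if (is.matrix(signal)) dim(out) <- dim(signal)
    if (is.array(signal)) dim(out) <- dim(signal)
    out
  })
}

# ---- geometry helpers (0-based voxel coordinates, isotropic grid) ----------

# Linear (1-based) indices of voxels whose centers lie within diameter/2 of
# the given 0-based center voxel. Errors if the sphere is clipped.
sphereVoxels <- function(center, diameter, dims, voxelSize = 1, name = "ROI") {
  r <- (diameter / 2) / voxelSize
  w <- ceiling(r)
  if (any(center - w < 0) || any(center + w > dims - 1))
    stop(sprintf("sphere for %s at (%s) clipped by the grid boundary", name,
                 paste(center, collapse = ",")))
  off <- as.matrix(expand.grid(x = -w:w, y = -w:w, z = -w:w))
  off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
  vox <- sweep(off, 2, center, "+")
  1L + vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3])
}

ellipsoidVoxels <- function(center, semi, dims) {
  w <- ceiling(semi)
  lo <- pmax(center - w, 0); hi <- pmin(center + w, dims - 1)
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  d <- sweep(g, 2, center, "-")
  keep <- (d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2 <= 1
  g <- g[keep, , drop = FALSE]
  1L + g[, 1] + dims[1] * (g[, 2] + dims[2] * g[, 3])
}

# Axisymmetric eigenvalues (l1 >= l2 = l3) with a given FA and MD.
axisymmetricEvals <- function(fa, md) {
  stopifnot(fa >= 0, fa < sqrt(3 / 2) / sqrt(1.5), md > 0) # fa < 1 for prolate
  delta <- fa * sqrt(3 / (9 - 6 * fa^2))
  c(md * (1 + 2 * delta), md * (1 - delta), md * (1 - delta))
}

# Diagonal 3x3 tensor from eigenvalues assigned to named axes.
diagTensor <- function(dxx, dyy, dzz) diag(c(dxx, dyy, dzz))

#' Phantom geometry and signal parameters
#'
#' Bundles the grid, the four perivascular ROI spheres, the two hippocampal
#' label ellipsoids, a brain-ellipsoid support mask, the baseline tensors for
#' every structure, and the signal amplitude / SNR. Tensors here are the
#' defaults used when no group preset modulates the phantom (e.g. isotropic
#' test phantoms); `buildSubjectPhantom()` overrides them from a preset.
#'
#' @param gridShape integer vector of 3 positive grid dimensions (voxels).
#' @param voxelSize isotropic voxel edge (mm).
#' @param rois data.frame with columns name, side, fiber, x, y, z (0-based
#'   voxel coordinates), diameter (mm); one row per ALPS ROI.
#' @param hippo data.frame with columns id, name, cx, cy, cz, ax, ay, az
#'   (centers and semi-axes, voxels); one row per hippocampal label.
#' @param brainCenter,brainSemi center and semi-axes of the brain support
#'   ellipsoid (voxels); the phantom mask is this ellipsoid united with all
#'   structures.
#' @param roiTensors named list (by ROI name) of 3x3 tensors (mm^2/s).
#' @param hippoTensors named list (by label id as character) of 3x3 tensors.
#' @param backgroundTensor 3x3 tensor for unlabeled in-mask voxels.
#' @param s0 non-diffusion-weighted amplitude.
#' @param snr s0 / sigma ratio of the Rician noise channels (> 0).
#' @return a validated list of class \code{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape, voxelSize, rois, hippo, brainCenter,
                        brainSemi, roiTensors, hippoTensors, backgroundTensor,
                        s0 = 1000, snr = 20) {
  stopifnot(length(gridShape) == 3, all(gridShape > 0), voxelSize > 0, snr > 0,
            s0 > 0)
  need <- c("name", "side", "fiber", "x", "y", "z", "diameter")
  if (!all(need %in% names(rois))) stop("rois lacks required columns")
  if (!all(c("projection", "association") %in% rois$fiber) ||
      !all(c("left", "right") %in% rois$side))
    stop("rois must cover both sides and both fiber systems")
  for (tn in c(roiTensors, hippoTensors, list(backgroundTensor))) {
    ev <- eigen(as.matrix(tn), symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < 0)) stop("all phantom tensor eigenvalues must be >= 0")
  }
  spec <- list(gridShape = as.integer(gridShape), voxelSize = voxelSize,
               rois = rois, hippo = hippo, brainCenter = brainCenter,
               brainSemi = brainSemi, roiTensors = roiTensors,
               hippoTensors = hippoTensors, backgroundTensor = backgroundTensor,
               s0 = s0, snr = snr)
  class(spec) <- "PhantomSpec"
  # fail early if any structure leaves the grid
  specStructureIndex(spec)
  spec
}

# Resolve all structure voxel index sets once per spec.
specStructureIndex <- function(spec) {
  dims <- spec$gridShape
  roiIdx <- lapply(seq_len(nrow(spec$rois)), function(i) {
    r <- spec$rois[i, ]
    sphereVoxels(c(r$x, r$y, r$z), r$diameter, dims, spec$voxelSize, r$name)
  })
  names(roiIdx) <- spec$rois$name
  hippoIdx <- lapply(seq_len(nrow(spec$hippo)), function(i) {
    h <- spec$hippo[i, ]
    ellipsoidVoxels(c(h$cx, h$cy, h$cz), c(h$ax, h$ay, h$az), dims)
  })
  names(hippoIdx) <- as.character(spec$hippo$id)
  brain <- ellipsoidVoxels(spec$brainCenter, spec$brainSemi, dims)
  # structures must not overlap, or painted ground truth would be polluted
  structs <- c(roiIdx, hippoIdx)
  all <- unlist(structs)
  if (anyDuplicated(all))
    stop("phantom structures (ROI spheres / hippocampal labels) overlap; ",
         "adjust the spec geometry")
  list(roi = roiIdx, hippo = hippoIdx, brain = brain)
}

# Default isotropic tensors for a plain (preset-free) phantom.
.defaultStructureTensors <- function(d = 0.75e-3) {
  list(roi = diagTensor(d, d, d), hippo = diagTensor(d, d, d),
       background = diagTensor(d, d, d))
}

#' Reduced-grid phantom specification
#'
#' A 64 x 64 x 32 voxel grid at 1 mm with re-homed ROI spheres (preserving the
#' template's one-voxel z-asymmetry between hemispheres), two ellipsoidal
#' hippocampal labels (IDs 37 left / 38 right, the conventional bilateral
#' hippocampus labels of the 90-region parcellation) and a brain-ellipsoid
#' support mask. This grid makes full-pipeline cohort runs cheap while keeping
#' every geometric property of the template-space analysis.
#'
#' @param snr s0/sigma of the Rician noise (default 20).
#' @param s0 signal amplitude (default 1000).
#' @param isotropicD if not NULL, every structure gets this isotropic
#'   diffusivity (mm^2/s) — useful for exactness tests.
#' @return a \code{PhantomSpec}.
#' @export
reducedPhantomSpec <- function(snr = 20, s0 = 1000, isotropicD = NULL) {
  rois <- data.frame(
    name = c("proj_L", "assoc_L", "proj_R", "assoc_R"),
    side = c("left", "left", "right", "right"),
    fiber = c("projection", "association", "projection", "association"),
    x = c(40L, 46L, 24L, 18L),
    y = c(32L, 32L, 32L, 32L),
    z = c(15L, 15L, 16L, 16L),
    diameter = 5,
    stringsAsFactors = FALSE)
  hippo <- data.frame(id = c(37L, 38L),
                      name = c("Hippocampus_L", "Hippocampus_R"),
                      cx = c(42L, 22L), cy = c(16L, 16L), cz = c(16L, 16L),
                      ax = 5, ay = 8, az = 4)
  if (is.null(isotropicD)) {
    d0 <- 0.6e-3; dF <- 1.5e-3
    roiT <- list(proj_L = diagTensor(1.0e-3, d0, dF),
                 assoc_L = diagTensor(1.0e-3, dF, d0),
                 proj_R = diagTensor(1.0e-3, d0, dF),
                 assoc_R = diagTensor(1.0e-3, dF, d0))
    ev <- axisymmetricEvals(0.17, 8.8e-4)
    hipT <- diagTensor(ev[2], ev[1], ev[3])
    hippoT <- list(`37` = hipT, `38` = hipT)
    bg <- diagTensor(0.75e-3, 0.75e-3, 0.75e-3)
  } else {
    t0 <- diagTensor(isotropicD, isotropicD, isotropicD)
    roiT <- list(proj_L = t0, assoc_L = t0, proj_R = t0, assoc_R = t0)
    hippoT <- list(`37` = t0, `38` = t0)
    bg <- t0
  }
  phantomSpec(gridShape = c(64L, 64L, 32L), voxelSize = 1, rois = rois,
              hippo = hippo, brainCenter = c(32, 24, 16),
              brainSemi = c(20, 16, 9), roiTensors = roiT,
              hippoTensors = hippoT, backgroundTensor = bg, s0 = s0, snr = snr)
}

#' Smoke-test phantom specification
#'
#' A 32 x 32 x 16 grid with proportionally shrunken structures, for smoke
#' profiles and fast unit tests. Geometrically equivalent to the reduced
#' grid (disjoint 5 mm ROI spheres, two hippocampal ellipsoids, brain
#' support mask), an order of magnitude fewer voxels.
#'
#' @inheritParams reducedPhantomSpec
#' @export
smokePhantomSpec <- function(snr = 20, s0 = 1000, isotropicD = NULL) {
  red <- reducedPhantomSpec(snr = snr, s0 = s0, isotropicD = isotropicD)
  rois <- red$rois
  rois$x <- c(19L, 25L, 13L, 7L)
  rois$y <- 16L
  rois$z <- c(7L, 7L, 8L, 8L)
  hippo <- data.frame(id = c(37L, 38L),
                      name = c("Hippocampus_L", "Hippocampus_R"),
                      cx = c(21L, 11L), cy = c(8L, 8L), cz = c(8L, 8L),
                      ax = 3, ay = 4, az = 3)
  phantomSpec(gridShape = c(32L, 32L, 16L), voxelSize = 1, rois = rois,
              hippo = hippo, brainCenter = c(16, 12, 8),
              brainSemi = c(13, 10, 6), roiTensors = red$roiTensors,
              hippoTensors = red$hippoTensors,
              backgroundTensor = red$backgroundTensor, s0 = s0, snr = snr)
}

#' Template-grid phantom specification
#'
#' The full 182 x 218 x 182 voxel 1 mm template grid with the four printed ROI
#' coordinates and anatomically plausible hippocampal ellipsoids. Heavy: meant
#' for realistic single-subject phantoms, not cohort test runs.
#'
#' @inheritParams reducedPhantomSpec
#' @export
templatePhantomSpec <- function(snr = 20, s0 = 1000, isotropicD = NULL) {
  red <- reducedPhantomSpec(snr = snr, s0 = s0, isotropicD = isotropicD)
  rois <- defaultRois()
  hippo <- data.frame(id = c(37L, 38L),
                      name = c("Hippocampus_L", "Hippocampus_R"),
                      cx = c(119L, 62L), cy = c(105L, 105L), cz = c(60L, 60L),
                      ax = 10, ay = 18, az = 9)
  phantomSpec(gridShape = c(182L, 218L, 182L), voxelSize = 1, rois = rois,
              hippo = hippo, brainCenter = c(90, 108, 91),
              brainSemi = c(72, 88, 75), roiTensors = red$roiTensors,
              hippoTensors = red$hippoTensors,
              backgroundTensor = red$backgroundTensor, s0 = s0, snr = snr)
}

# Draw subject-level structure tensors from a group preset (or take the
# spec's own baseline tensors when preset is NULL). All draws happen inside
# the caller's seed context. Returns list(roiTensors, hippoTensors,
# backgroundTensor, truth = list(...)).
drawSubjectTensors <- function(spec, preset) {
  if (is.null(preset)) {
    tens <- list(roiTensors = spec$roiTensors, hippoTensors = spec$hippoTensors,
                 backgroundTensor = spec$backgroundTensor)
    tens$truth <- NULL
    return(tens)
  }
  a <- preset$alps
  zs <- rnorm(1); zL <- rnorm(1); zR <- rnorm(1)
  mix <- function(z) sqrt(a$rho) * zs + sqrt(1 - a$rho) * z
  loc <- function(m, sig) if (a$locType == "mean") m * exp(-sig^2 / 2) else m
  # calL/calR: location recovery calibration (ground-truth location is the
  # table value divided by the pipeline's recovery factor; see
  # scripts/calibrate_presets.R)
  A_L <- a$calL * loc(a$locL, a$sigL) * exp(a$sigL * mix(zL))
  A_R <- a$calR * loc(a$locR, a$sigR) * exp(a$sigR * mix(zR))
  base <- exp(rnorm(1, 0, a$baseSigma))
  d0 <- a$dPerp * base; dF <- a$dFiber * base
  roiT <- list(proj_L  = diagTensor(A_L * d0, d0, dF),
               assoc_L = diagTensor(A_L * d0, dF, d0),
               proj_R  = diagTensor(A_R * d0, d0, dF),
               assoc_R = diagTensor(A_R * d0, dF, d0))
  h <- preset$hippo
  hippoT <- list()
  truthHip <- list()
  for (id in as.character(spec$hippo$id)) {
    fa <- min(max(rnorm(1, h$faMean, h$faSd), 0.02), 0.9)
    md <- max(rnorm(1, h$mdMean, h$mdSd), 1e-4)
    ev <- axisymmetricEvals(fa, md)
    hippoT[[id]] <- diagTensor(ev[2], ev[1], ev[3])
    truthHip[[id]] <- c(fa = fa, md = md, ad = ev[1], rd = (ev[2] + ev[3]) / 2)
  }
  list(roiTensors = roiT, hippoTensors = hippoT,
       backgroundTensor = spec$backgroundTensor,
       truth = list(alps = c(left = A_L, right = A_R, mean = (A_L + A_R) / 2),
                    hippo = truthHip))
}

# Paint the voxelwise true tensor field: background everywhere in the brain
# mask, hippocampal labels, then ROI spheres on top.
paintTensorField <- function(spec, tensors, idx) {
  dims <- spec$gridShape
  nv <- prod(dims)
  maskIdx <- sort(unique(c(idx$brain, unlist(idx$roi), unlist(idx$hippo))))
  mask <- array(FALSE, dims)
  mask[maskIdx] <- TRUE
  # one row of six unique elements per structure; voxel -> structure lookup
  six <- function(t) c(t[1, 1], t[2, 2], t[3, 3], t[1, 2], t[1, 3], t[2, 3])
  T6 <- rbind(0, six(tensors$backgroundTensor))
  structOf <- integer(nv)
  structOf[maskIdx] <- 2L
  for (id in names(idx$hippo)) {
    T6 <- rbind(T6, six(tensors$hippoTensors[[id]]))
    structOf[idx$hippo[[id]]] <- nrow(T6)
  }
  for (nm in names(idx$roi)) {
    T6 <- rbind(T6, six(tensors$roiTensors[[nm]]))
    structOf[idx$roi[[nm]]] <- nrow(T6)
  }
  D <- T6[pmax(structOf, 1L), , drop = FALSE]
  colnames(D) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  structTensors <- c(list(NULL, tensors$backgroundTensor),
                     tensors$hippoTensors[names(idx$hippo)],
                     tensors$roiTensors[names(idx$roi)])
  list(D = D, mask = mask, maskIdx = maskIdx, structOf = structOf,
       structTensors = structTensors)
}

#' Build a single-subject DWI phantom
#'
#' Draws subject-level diffusivities from a group preset (if given), paints
#' the template-space tensor field, synthesizes the diffusion-weighted signal
#' through the monoexponential forward model and adds Rician noise at the
#' spec's SNR. Ground-truth ALPS values are recomputed from the painted field
#' itself (not from the drawn parameters) so they are exact by construction.
#'
#' @param spec a \code{PhantomSpec}.
#' @param preset a \code{GroupPreset} from [groupPreset()], or NULL to use the
#'   spec's baseline tensors unchanged.
#' @param scheme an [AcquisitionScheme-class].
#' @param subjectSeed integer seed controlling this subject's draws and noise.
#' @param noise logical; FALSE yields a noise-free phantom.
#' @param imaging logical; FALSE skips signal synthesis (the painted field and
#'   ground truth are still produced; \code{dwi} is NULL). The subject's
#'   random draws are identical either way.
#' @param .idx precomputed [specStructureIndex()] result (internal; cohort
#'   generation resolves the geometry once and reuses it).
#' @return a list of class \code{SubjectPhantom}: \code{dwi}
#'   ([DWIDataset-class]), \code{groundTruth} (true ALPS indices, ROI
#'   diffusivities, hippocampal metrics), \code{trueField}
#'   ([TensorField-class]) and \code{subjectId}.
#' @export
buildSubjectPhantom <- function(spec, preset = NULL, scheme, subjectSeed = 1L,
                                noise = TRUE, imaging = TRUE, .idx = NULL) {
  stopifnot(inherits(spec, "PhantomSpec"), is(scheme, "AcquisitionScheme"))
  idx <- if (is.null(.idx)) specStructureIndex(spec) else .idx
  tensors <- withSeed(deriveSeed(subjectSeed, "tensors"),
                      drawSubjectTensors(spec, preset))
  field <- paintTensorField(spec, tensors, idx)

  # ground truth ALPS straight from the painted field (exact ROI means)
  truthAlps <- alpsFromTensorRows(field$D, idx$roi)
  truthHippo <- do.call(rbind, lapply(as.character(spec$hippo$id), function(id) {
    ev <- sort(eigen(tensors$hippoTensors[[id]], symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    data.frame(id = as.integer(id),
               fa = faFromEvals(ev[1], ev[2], ev[3]),
               md = mean(ev), ad = ev[1], rd = (ev[2] + ev[3]) / 2)
  }))

  # synthesize signals: the field is piecewise constant, so evaluate the
  # forward model once per structure and broadcast by a single index lookup
  dwi <- NULL
  if (imaging) {
  S <- do.call(rbind, lapply(field$structTensors[-1], simulateSignal,
                             scheme = scheme, s0 = spec$s0))
  signal <- S[field$structOf[field$maskIdx] - 1L, , drop = FALSE]
  if (noise)
    signal <- addRicianNoise(signal, spec$s0 / spec$snr,
                             seed = deriveSeed(subjectSeed, "noise"))
  dwi <- new("DWIDataset", signal = signal, mask = field$mask, scheme = scheme,
             voxelSize = spec$voxelSize)
  }
  trueField <- new("TensorField", D = field$D, mask = field$mask,
                   flags = rep(FALSE, prod(spec$gridShape)),
                   residualNorm = numeric(prod(spec$gridShape)),
                   voxelSize = spec$voxelSize)
  out <- list(dwi = dwi, trueField = trueField,
              groundTruth = list(alps = truthAlps$indices,
                                 roiMeans = truthAlps$roiMeans,
                                 hippo = truthHippo),
              subjectId = sprintf("sub-%06d", as.integer(subjectSeed %% 1e6)),
              seed = subjectSeed)
  class(out) <- "SubjectPhantom"
  out
}

# ALPS formula applied to tensor-field rows over given ROI voxel sets.
alpsFromTensorRows <- function(D, roiIdx) {
  m <- function(col, nm) mean(D[roiIdx[[nm]], col])
  rm <- c(Dxproj_L = m(1, "proj_L"), Dxassoc_L = m(1, "assoc_L"),
          Dyproj_L = m(2, "proj_L"), Dzassoc_L = m(3, "assoc_L"),
          Dxproj_R = m(1, "proj_R"), Dxassoc_R = m(1, "assoc_R"),
          Dyproj_R = m(2, "proj_R"), Dzassoc_R = m(3, "assoc_R"))
  left <- mean(rm[c("Dxproj_L", "Dxassoc_L")]) / mean(rm[c("Dyproj_L", "Dzassoc_L")])
  right <- mean(rm[c("Dxproj_R", "Dxassoc_R")]) / mean(rm[c("Dyproj_R", "Dzassoc_R")])
  list(roiMeans = rm,
       indices = c(left = left, right = right, mean = (left + right) / 2))
}

faFromEvals <- function(l1, l2, l3) {
  lb <- (l1 + l2 + l3) / 3
  den <- sqrt(l1^2 + l2^2 + l3^2)
  if (den == 0) return(0)
  sqrt(3 / 2) * sqrt((l1 - lb)^2 + (l2 - lb)^2 + (l3 - lb)^2) / den
}

#' Generate a full phantom cohort
#'
#' Draws one subject phantom per row of the design (three groups with the
#' given sizes) plus a covariate table per the group presets. Subject seeds
#' are derived deterministically from (seed, group, index), so a single-group
#' cohort at the same seed reproduces exactly the corresponding subset of the
#' full cohort.
#'
#' @param presets named list of three \code{GroupPreset}s (HC, DMNC, DMMCI) —
#'   any subset of groups is allowed.
#' @param sizes integer vector of group sizes, same length/order as presets.
#' @param spec a \code{PhantomSpec}.
#' @param scheme an [AcquisitionScheme-class].
#' @param seed integer cohort seed.
#' @param keepImaging logical; FALSE discards imaging and returns only the
#'   covariate/ground-truth table (fast, constant memory).
#' @param imaging logical; FALSE skips signal synthesis entirely (ground
#'   truth and covariates only — useful for distribution-level checks).
#' @param analyze optional function(SubjectPhantom) returning a one-row
#'   data.frame of derived metrics; applied per subject with imaging then
#'   discarded (streaming mode for full-pipeline cohort runs).
#' @param noise logical; passed to [buildSubjectPhantom()].
#' @return list with \code{subjects} (list of SubjectPhantom, possibly empty),
#'   \code{covariates} (data.frame: subject_id, group, covariates, ground-truth
#'   ALPS/hippocampal columns and any \code{analyze} outputs), and
#'   \code{provenance}.
#' @export
generateCohort <- function(presets, sizes, spec, scheme, seed = 1L,
                           keepImaging = TRUE, analyze = NULL, noise = TRUE,
                           imaging = TRUE) {
  stopifnot(length(presets) == length(sizes), all(sizes > 0))
  groups <- vapply(presets, function(p) p$label, character(1))
  idx <- specStructureIndex(spec)   # resolved once for the whole cohort
  subjects <- list()
  rows <- list()
  for (gi in seq_along(presets)) {
    preset <- presets[[gi]]
    g <- groups[gi]
    cov <- drawCovariates(preset, sizes[gi], deriveSeed(seed, g, "covariates"))
    for (i in seq_len(sizes[gi])) {
      sseed <- deriveSeed(seed, g, i)
      ph <- buildSubjectPhantom(spec, preset, scheme, subjectSeed = sseed,
                                noise = noise, imaging = imaging, .idx = idx)
      id <- sprintf("%s-%03d", g, i)
      ph$subjectId <- id
      truth <- data.frame(
        subject_id = id, group = g,
        truth_alps_left = ph$groundTruth$alps["left"],
        truth_alps_right = ph$groundTruth$alps["right"],
        truth_alps_mean = ph$groundTruth$alps["mean"],
        stringsAsFactors = FALSE)
      hip <- ph$groundTruth$hippo
      for (j in seq_len(nrow(hip))) {
        side <- if (hip$id[j] == 37) "left" else "right"
        for (mname in c("fa", "md", "ad", "rd"))
          truth[[paste0("truth_hippo_", mname, "_", side)]] <- hip[[mname]][j]
      }
      row <- cbind(truth, cov[i, , drop = FALSE])
      if (!is.null(analyze)) row <- cbind(row, analyze(ph))
      rows[[length(rows) + 1L]] <- row
      if (keepImaging) subjects[[id]] <- ph
    }
  }
  covariates <- do.call(rbind, rows)
  rownames(covariates) <- NULL
  list(subjects = subjects, covariates = covariates,
       provenance = list(seed = seed, groups = groups, sizes = sizes,
                         snr = spec$snr, grid = spec$gridShape))
}
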
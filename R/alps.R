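# ALPS-index computation from template-space spherical ROIs.

#' The four template-space ALPS ROIs
#'
#' Spherical regions of interest at the published template coordinates, all
#' with diameter 5 mm: left projection fiber (116,109,99), left association
#' fiber (126,109,99), right projection fiber (64,109,101) and right
#' association fiber (54,109,101), interpreted as 0-based voxel indices into
#' the 182 x 218 x 182 1 mm template grid in its stored orientation. The
#' indexing convention is not universal, so a \code{oneBased} switch converts
#' coordinates printed as 1-based indices.
#'
#' @param oneBased treat the printed coordinates as 1-based voxel indices
#'   (internally shifted down by one).
#' @return data.frame with columns name, side, fiber, x, y, z (0-based voxel
#'   coordinates) and diameter (mm).
#' @export
defaultRois <- function(oneBased = FALSE) {
  rois <- data.frame(
    name = c("proj_L", "assoc_L", "proj_R", "assoc_R"),
    side = c("left", "left", "right", "right"),
    fiber = c("projection", "association", "projection", "association"),
    x = c(116L, 126L, 64L, 54L),
    y = c(109L, 109L, 109L, 109L),
    z = c(99L, 99L, 101L, 101L),
    diameter = 5,
    stringsAsFactors = FALSE)
  if (oneBased) {
    rois$x <- rois$x - 1L; rois$y <- rois$y - 1L; rois$z <- rois$z - 1L
  }
  rois
}

#' Mean of a scalar map over one spherical ROI
#'
#' Unweighted mean over all voxels whose centers lie within diameter/2 of the
#' center-voxel center (voxel-center distance <= radius, so the count is
#' bit-stable: 81 voxels for a 5 mm sphere on a 1 mm grid). By default all
#' sphere voxels contribute; with a mask, only in-mask voxels are averaged and
#' a warning names any ROI not fully covered.
#'
#' @param map numeric 3-D array.
#' @param roi one-row data.frame with columns name, x, y, z (0-based) and
#'   diameter (mm).
#' @param voxelSize voxel edge (mm).
#' @param mask optional logical array; voxels outside it are dropped from the
#'   mean.
#' @return scalar mean.
#' @export
roiMean <- function(map, roi, voxelSize = 1, mask = NULL) {
  dims <- dim(map)
  vox <- sphereVoxels(c(roi$x, roi$y, roi$z), roi$diameter, dims, voxelSize,
                      name = roi$name)
  if (!is.null(mask)) {
    inm <- mask[vox]
    if (!all(inm))
      warning(sprintf("ROI %s: only %d/%d sphere voxels inside the mask",
                      roi$name, sum(inm), length(vox)))
    vox <- vox[inm]
  }
  mean(map[vox])
}

#' Compute left, right and average ALPS-indices
#'
#' For each hemisphere the x-axis diffusivity (dxx) is averaged over the
#' projection- and association-fiber ROIs, the y-axis diffusivity (dyy) over
#' the projection ROI and the z-axis diffusivity (dzz) over the association
#' ROI; the ALPS-index is
#' mean(Dxproj, Dxassoc) / mean(Dyproj, Dzassoc), and the average index is the
#' mean of the two sides.
#'
#' @param maps a [DiffusivityMaps-class].
#' @param rois data.frame of four ROIs covering each (side, fiber)
#'   combination, as from [defaultRois()].
#' @param useMask restrict ROI means to the fitted mask (off by default).
#' @return an [ALPSResult-class].
#' @export
computeAlps <- function(maps, rois, useMask = FALSE) {
  stopifnot(is(maps, "DiffusivityMaps"))
  combos <- paste(rois$side, rois$fiber)
  need <- c("left projection", "left association",
            "right projection", "right association")
  if (!setequal(combos, need) || nrow(rois) != 4)
    stop("rois must contain exactly one ROI per (side, fiber) combination; ",
         "missing: ", paste(setdiff(need, combos), collapse = ", "))
  mask <- if (useMask) maps@mask else NULL
  pick <- function(side, fiber) rois[rois$side == side & rois$fiber == fiber, ]
  vs <- maps@voxelSize
  rm <- c(
    Dxproj_L  = roiMean(maps@dxx, pick("left", "projection"), vs, mask),
    Dxassoc_L = roiMean(maps@dxx, pick("left", "association"), vs, mask),
    Dyproj_L  = roiMean(maps@dyy, pick("left", "projection"), vs, mask),
    Dzassoc_L = roiMean(maps@dzz, pick("left", "association"), vs, mask),
    Dxproj_R  = roiMean(maps@dxx, pick("right", "projection"), vs, mask),
    Dxassoc_R = roiMean(maps@dxx, pick("right", "association"), vs, mask),
    Dyproj_R  = roiMean(maps@dyy, pick("right", "projection"), vs, mask),
    Dzassoc_R = roiMean(maps@dzz, pick("right", "association"), vs, mask))
  denL <- mean(rm[c("Dyproj_L", "Dzassoc_L")])
  denR <- mean(rm[c("Dyproj_R", "Dzassoc_R")])
  if (denL <= 0 || denR <= 0)
    stop(sprintf(paste0("non-positive ALPS denominator (left %.3g, right %.3g);",
                        " ROI means: %s"),
                 denL, denR, paste(sprintf("%s=%.3g", names(rm), rm),
                                   collapse = ", ")))
  left <- mean(rm[c("Dxproj_L", "Dxassoc_L")]) / denL
  right <- mean(rm[c("Dxproj_R", "Dxassoc_R")]) / denR
  new("ALPSResult", roiMeans = rm, left = left, right = right,
      mean = (left + right) / 2)
}

#' Mirror ROI definitions across the grid's x mid-plane
#'
#' Reflects each ROI center (0-based x -> nx - 1 - x) and swaps the side
#' labels, so that ALPS computed on x-reflected maps with the mirrored ROIs
#' swaps the left and right indices exactly.
#'
#' @param rois ROI data.frame.
#' @param nx grid extent along x (voxels).
#' @export
mirrorRois <- function(rois, nx) {
  rois$x <- nx - 1L - rois$x
  rois$side <- ifelse(rois$side == "left", "right", "left")
  rois$name <- ifelse(grepl("_L$", rois$name), sub("_L$", "_R", rois$name),
                      sub("_R$", "_L", rois$name))
  rois
}

#' Reflect diffusivity maps across the x mid-plane
#' @param maps a [DiffusivityMaps-class]
#' @return a [DiffusivityMaps-class] with every volume x-reversed
#' @export
mirrorMaps <- function(maps) {
  stopifnot(is(maps, "DiffusivityMaps"))
  rev1 <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  dims <- dim(maps@mask)
  perm <- as.vector(array(seq_len(prod(dims)), dims)[dims[1]:1, , ])
  new("DiffusivityMaps",
      dxx = rev1(maps@dxx), dyy = rev1(maps@dyy), dzz = rev1(maps@dzz),
      fa = rev1(maps@fa), md = rev1(maps@md), ad = rev1(maps@ad),
      rd = rev1(maps@rd), evals = maps@evals[perm, , drop = FALSE],
      flags = maps@flags[perm], mask = rev1(maps@mask),
      voxelSize = maps@voxelSize)
}
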
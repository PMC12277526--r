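# Standard-format I/O: NIfTI volumes, FSL-style bvals/bvecs, cohort CSV.

#' Write a DWI dataset as NIfTI + FSL gradient tables
#'
#' Produces \code{<prefix>.nii.gz} (4-D, float64 so phantom signals round-trip
#' exactly), \code{<prefix>.bval}
#' (one row of b-values) and \code{<prefix>.bvec} (three rows of direction
#' components), plus \code{<prefix>_mask.nii.gz}.
#'
#' @param dataset a [DWIDataset-class].
#' @param prefix output path prefix.
#' @return the paths, invisibly.
#' @export
writeDwi <- function(dataset, prefix) {
  stopifnot(is(dataset, "DWIDataset"))
  vs <- dataset@voxelSize
  img <- RNifti::asNifti(as4D(dataset), pixdim = c(vs, vs, vs, 1),
                         datatype = "double")
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  mask <- paste0(prefix, "_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(dataset@mask),
                                           dim(dataset@mask)),
                                     pixdim = rep(vs, 3), datatype = "uint8"),
                     mask)
  bval <- paste0(prefix, ".bval")
  writeLines(paste(format(dataset@scheme@bvals, trim = TRUE), collapse = " "),
             bval)
  bvec <- paste0(prefix, ".bvec")
  writeLines(apply(t(dataset@scheme@bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec)
  invisible(c(nii = nii, mask = mask, bval = bval, bvec = bvec))
}

#' Read a DWI dataset from NIfTI + FSL gradient tables
#'
#' Directions whose norms are off unity by more than 1e-3 are re-normalized
#' with a warning; smaller deviations are re-normalized silently.
#'
#' @param niftiPath 4-D NIfTI image.
#' @param bvalsPath FSL bvals text file (one row).
#' @param bvecsPath FSL bvecs text file (three rows).
#' @param maskPath optional mask NIfTI; when absent, voxels with positive
#'   mean b0 signal form the mask.
#' @return a [DWIDataset-class].
#' @export
readDwi <- function(niftiPath, bvalsPath, bvecsPath, maskPath = NULL) {
  img <- RNifti::readNifti(niftiPath)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("expected a 4-D NIfTI image")
  bvals <- scan(bvalsPath, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvecsPath))
  if (nrow(bv) != 3) stop("bvecs must have three rows")
  bvecs <- t(bv)
  dimnames(bvecs) <- NULL
  if (length(bvals) != dim(arr)[4] || nrow(bvecs) != dim(arr)[4])
    stop(sprintf("gradient table length (%d bvals, %d bvecs) does not match %d volumes",
                 length(bvals), nrow(bvecs), dim(arr)[4]))
  dwi <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[dwi] - 1) > 1e-3))
    warning(sprintf("%d gradient directions off unit norm by > 1e-3; re-normalized",
                    sum(abs(nrm[dwi] - 1) > 1e-3)))
  bvecs[dwi, ] <- bvecs[dwi, , drop = FALSE] / nrm[dwi]
  bvecs[!dwi, ] <- 0
  vs <- RNifti::pixdim(img)[1]
  mask <- if (!is.null(maskPath)) {
    as.array(RNifti::readNifti(maskPath)) > 0
  } else {
    b0 <- which(bvals == 0)
    apply(arr[, , , b0, drop = FALSE], 1:3, mean) > 0
  }
  storage.mode(mask) <- "logical"
  nv <- prod(dim(arr)[1:3])
  sigAll <- matrix(arr, nv, dim(arr)[4])
  new("DWIDataset", signal = sigAll[which(as.vector(mask)), , drop = FALSE],
      mask = array(mask, dim(arr)[1:3]),
      scheme = new("AcquisitionScheme", bvals = bvals, bvecs = bvecs),
      voxelSize = if (is.na(vs) || vs <= 0) 1 else vs)
}

#' Write a scalar map as NIfTI (float32)
#' @param map numeric 3-D array.
#' @param path output path.
#' @param voxelSize voxel edge (mm).
#' @export
writeScalarMap <- function(map, path, voxelSize = 1) {
  RNifti::writeNifti(RNifti::asNifti(map, pixdim = rep(voxelSize, 3),
                                     datatype = "float"), path)
  invisible(path)
}

#' Read a label volume from NIfTI (+ optional JSON dictionary)
#' @param niftiPath integer label image.
#' @param dictionaryPath optional JSON file mapping id to region name.
#' @export
readLabelVolume <- function(niftiPath, dictionaryPath = NULL) {
  arr <- as.array(RNifti::readNifti(niftiPath))
  vs <- RNifti::pixdim(RNifti::readNifti(niftiPath))[1]
  ids <- sort(unique(as.vector(arr))); ids <- ids[ids != 0]
  dict <- if (!is.null(dictionaryPath)) {
    d <- jsonlite::read_json(dictionaryPath, simplifyVector = TRUE)
    setNames(as.character(unlist(d)), names(d))
  } else setNames(sprintf("region_%d", ids), as.character(ids))
  labelVolume(array(as.integer(round(arr)), dim(arr)), dict,
              if (is.na(vs) || vs <= 0) 1 else vs)
}

#' Read ROI definitions from JSON
#'
#' The file holds four named entries with side, fiber, center (x, y, z) and
#' diameter, overriding [defaultRois()].
#' @param path JSON file.
#' @export
readRoisJson <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- do.call(rbind, lapply(names(d), function(nm) {
    e <- d[[nm]]
    data.frame(name = nm, side = e$side, fiber = e$fiber,
               x = e$center[1], y = e$center[2], z = e$center[3],
               diameter = e$diameter, stringsAsFactors = FALSE)
  }))
  rois
}

#' Write / read the cohort table as CSV
#'
#' Columns: subject_id, group, the clinical and cognitive covariates, the
#' ground-truth columns (truth_*) for synthetic cohorts, and the pipeline
#' metrics (alps_*, hippo_*).
#' @param cohort data.frame.
#' @param path CSV path.
#' @export
writeCohortCsv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
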
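#' Number of measurements in a scheme or dataset
#' @param x an AcquisitionScheme or DWIDataset
#' @export
setGeneric("nMeasurements", function(x) standardGeneric("nMeasurements"))

#' b-values of a scheme or dataset
#' @param x an AcquisitionScheme or DWIDataset
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' Gradient directions (one row per measurement)
#' @param x an AcquisitionScheme or DWIDataset
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))

#' Spatial grid dimensions
#' @param x an object with a 3-D grid
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Voxel edge length (mm)
#' @param x an object with a voxel size
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Expand a DWIDataset to a full 4-D array
#' @param x a DWIDataset
#' @export
setGeneric("as4D", function(x) standardGeneric("as4D"))

#' @describeIn nMeasurements scheme method
#' @export
setMethod("nMeasurements", "AcquisitionScheme", function(x) length(x@bvals))
#' @describeIn nMeasurements dataset method
#' @export
setMethod("nMeasurements", "DWIDataset", function(x) ncol(x@signal))

#' @describeIn bValues scheme method
#' @export
setMethod("bValues", "AcquisitionScheme", function(x) x@bvals)
#' @describeIn bValues dataset method
#' @export
setMethod("bValues", "DWIDataset", function(x) x@scheme@bvals)

#' @describeIn bVectors scheme method
#' @export
setMethod("bVectors", "AcquisitionScheme", function(x) x@bvecs)
#' @describeIn bVectors dataset method
#' @export
setMethod("bVectors", "DWIDataset", function(x) x@scheme@bvecs)

#' @describeIn gridDim dataset method
#' @export
setMethod("gridDim", "DWIDataset", function(x) dim(x@mask))
#' @describeIn gridDim tensor-field method
#' @export
setMethod("gridDim", "TensorField", function(x) dim(x@mask))
#' @describeIn gridDim maps method
#' @export
setMethod("gridDim", "DiffusivityMaps", function(x) dim(x@mask))
#' @describeIn gridDim label-volume method
#' @export
setMethod("gridDim", "LabelVolume", function(x) dim(x@labels))

#' @describeIn voxelSize dataset method
#' @export
setMethod("voxelSize", "DWIDataset", function(x) x@voxelSize)
#' @describeIn voxelSize tensor-field method
#' @export
setMethod("voxelSize", "TensorField", function(x) x@voxelSize)
#' @describeIn voxelSize maps method
#' @export
setMethod("voxelSize", "DiffusivityMaps", function(x) x@voxelSize)
#' @describeIn voxelSize label-volume method
#' @export
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)

#' @describeIn as4D expand in-mask signal rows into a dense array
#' @export
setMethod("as4D", "DWIDataset", function(x) {
  dm <- dim(x@mask)
  out <- array(0, c(dm, ncol(x@signal)))
  idx <- which(as.vector(x@mask))
  nv <- prod(dm)
  for (k in seq_len(ncol(x@signal)))
    out[idx + (k - 1L) * nv] <- x@signal[, k]
  out
})

#' Extract the scheme of a dataset
#' @param x a DWIDataset
#' @export
scheme <- function(x) {
  stopifnot(is(x, "DWIDataset"))
  x@scheme
}

#' Signal matrix (in-mask voxels x measurements)
#' @param x a DWIDataset
#' @export
signalMatrix <- function(x) {
  stopifnot(is(x, "DWIDataset"))
  x@signal
}

#' Brain mask of a dataset, tensor field or maps object
#' @param x a DWIDataset, TensorField or DiffusivityMaps
#' @export
brainMask <- function(x) {
  stopifnot(is(x, "DWIDataset") || is(x, "TensorField") || is(x, "DiffusivityMaps"))
  x@mask
}

#' The three ALPS-indices of an ALPSResult
#' @param x an ALPSResult
#' @return named numeric vector (left, right, mean)
#' @export
alpsIndices <- function(x) {
  stopifnot(is(x, "ALPSResult"))
  c(left = x@left, right = x@right, mean = x@mean)
}

#' The eight ROI mean diffusivities of an ALPSResult
#' @param x an ALPSResult
#' @export
roiMeans <- function(x) {
  stopifnot(is(x, "ALPSResult"))
  x@roiMeans
}

#' Scalar map accessor
#' @param x a DiffusivityMaps object
#' @param which one of dxx, dyy, dzz, fa, md, ad, rd
#' @export
scalarMap <- function(x, which = c("fa", "md", "ad", "rd", "dxx", "dyy", "dzz")) {
  stopifnot(is(x, "DiffusivityMaps"))
  slot(x, match.arg(which))
}

setMethod("show", "AcquisitionScheme", function(object) {
  shells <- sort(unique(object@bvals))
  cat("AcquisitionScheme:", length(object@bvals), "measurements,",
      sum(object@bvals == 0), "b0;",
      "shells (s/mm^2):", paste(shells, collapse = ", "), "\n")
})

setMethod("show", "DWIDataset", function(object) {
  cat("DWIDataset:", paste(dim(object@mask), collapse = " x "), "grid,",
      ncol(object@signal), "measurements,", sum(object@mask), "in-mask voxels,",
      "voxel", object@voxelSize, "mm\n")
})

setMethod("show", "TensorField", function(object) {
  cat("TensorField:", paste(dim(object@mask), collapse = " x "), "grid,",
      sum(object@mask), "fitted voxels,", sum(object@flags), "flagged\n")
})

setMethod("show", "DiffusivityMaps", function(object) {
  inm <- as.vector(object@mask) & !object@flags
  cat("DiffusivityMaps:", paste(dim(object@mask), collapse = " x "), "grid;",
      "median FA", signif(median(as.vector(object@fa)[inm]), 3),
      "median MD", signif(median(as.vector(object@md)[inm]), 3), "mm^2/s\n")
})

setMethod("show", "ALPSResult", function(object) {
  cat(sprintf("ALPSResult: left %.4f  right %.4f  mean %.4f\n",
              object@left, object@right, object@mean))
})

setMethod("show", "LabelVolume", function(object) {
  ids <- sort(unique(as.vector(object@labels)))
  ids <- ids[ids != 0]
  cat("LabelVolume:", paste(dim(object@labels), collapse = " x "), "grid,",
      length(ids), "regions:",
      paste(sprintf("%s=%s", ids, object@dictionary[as.character(ids)]),
            collapse = ", "), "\n")
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("StatResult [%s] %s: %s = %.4g, p = %.4g\n",
              object@route, object@test,
              if (length(names(object@statistic))) names(object@statistic)[1] else "stat",
              object@statistic[1], object@p[1]))
  if (nrow(object@posthoc)) {
    cat("  post hoc:\n")
    print(object@posthoc, row.names = FALSE)
  }
})
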
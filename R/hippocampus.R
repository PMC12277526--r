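# Atlas-based regional summaries of scalar diffusion maps.

#' Construct a LabelVolume
#'
#' @param labels integer 3-D array of region IDs (0 = background).
#' @param dictionary named character vector, ID (as name) to region name.
#' @param voxelSize voxel edge (mm).
#' @return a [LabelVolume-class].
#' @export
labelVolume <- function(labels, dictionary, voxelSize = 1) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, dictionary = dictionary,
      voxelSize = voxelSize)
}

#' Synthetic bilateral-hippocampus atlas for a phantom spec
#'
#' Builds a label volume with the spec's two hippocampal ellipsoids under the
#' conventional bilateral hippocampus IDs (37 left, 38 right) of the
#' 90-region parcellation. This is a synthetic stand-in so that tests and
#' phantom pipelines run without any atlas download; real atlas files are
#' supplied by the user as NIfTI paths.
#'
#' @param spec a \code{PhantomSpec}.
#' @return a [LabelVolume-class].
#' @export
syntheticHippocampusAtlas <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  lab <- array(0L, spec$gridShape)
  dict <- character()
  for (i in seq_len(nrow(spec$hippo))) {
    h <- spec$hippo[i, ]
    lab[ellipsoidVoxels(c(h$cx, h$cy, h$cz), c(h$ax, h$ay, h$az),
                        spec$gridShape)] <- h$id
    dict[as.character(h$id)] <- h$name
  }
  labelVolume(lab, dict, spec$voxelSize)
}

#' Regional means of FA/MD/AD/RD over atlas labels
#'
#' Unweighted mean of each scalar map over the voxels of each requested
#' label. Voxels flagged during fitting (degenerate or excluded) are dropped
#' from the means and counted.
#'
#' @param maps a [DiffusivityMaps-class].
#' @param labels a [LabelVolume-class] on the same grid.
#' @param regionIds integer IDs to summarise; every ID must be present and
#'   non-empty.
#' @return data.frame with one row per region: id, name, n_voxels,
#'   n_excluded, fa, md, ad, rd.
#' @export
aggregateRegionMetrics <- function(maps, labels, regionIds = c(37L, 38L)) {
  stopifnot(is(maps, "DiffusivityMaps"), is(labels, "LabelVolume"))
  if (!identical(dim(maps@mask), dim(labels@labels)))
    stop("label volume grid does not match the maps grid")
  lab <- as.vector(labels@labels)
  out <- lapply(regionIds, function(id) {
    vox <- which(lab == id)
    if (!length(vox))
      stop("requested label ", id, " is absent or empty in the label volume")
    good <- vox[!maps@flags[vox]]
    if (!length(good))
      stop("label ", id, " contains no usable (unflagged) voxels")
    data.frame(id = id,
               name = if (as.character(id) %in% names(labels@dictionary))
                 labels@dictionary[[as.character(id)]] else NA_character_,
               n_voxels = length(good), n_excluded = length(vox) - length(good),
               fa = mean(maps@fa[good]), md = mean(maps@md[good]),
               ad = mean(maps@ad[good]), rd = mean(maps@rd[good]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
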
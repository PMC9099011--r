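#' Voxel spacing accessor
#'
#' @param x a \linkS4class{VoxelVolume}.
#' @return numeric(3) spacing in mm along (row, col, slice).
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "VoxelVolume", function(x) x@spacing)

#' @describeIn VoxelVolume-class volume dimensions (rows, cols, slices).
#' @param x a VoxelVolume.
#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@data))

#' @describeIn LabelMap-class label-map dimensions.
#' @param x a LabelMap.
#' @export
setMethod("dim", "LabelMap", function(x) dim(x@labels))

#' Intensity grid accessor
#'
#' @param x a \linkS4class{VoxelVolume}.
#' @return the 3D intensity array.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setMethod("intensities", "VoxelVolume", function(x) x@data)

#' Label grid accessor
#'
#' @param x a \linkS4class{LabelMap}.
#' @return the 3D integer label array.
#' @export
setGeneric("labels3d", function(x) standardGeneric("labels3d"))

#' @rdname labels3d
#' @export
setMethod("labels3d", "LabelMap", function(x) x@labels)

#' Structure table accessor
#'
#' @param x a \linkS4class{StructureCatalog}.
#' @return data.frame of structures.
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))

#' @rdname structures
#' @export
setMethod("structures", "StructureCatalog", function(x) x@structures)

#' Goal (tumor) structure id of a catalog
#'
#' @param x a \linkS4class{StructureCatalog}.
#' @return integer id of the goal structure.
#' @export
setGeneric("goalId", function(x) standardGeneric("goalId"))

#' @rdname goalId
#' @export
setMethod("goalId", "StructureCatalog", function(x) {
  df <- x@structures
  as.integer(df$id[df$is_goal])
})

#' Number of admissible nodes in an environment
#'
#' @param x a \linkS4class{QEnvironment}.
#' @return integer node count.
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname nodeCount
#' @export
setMethod("nodeCount", "QEnvironment", function(x) sum(x@admissible))

#' Start states of an environment
#'
#' @param x a \linkS4class{QEnvironment}.
#' @return integer matrix (k x 3).
#' @export
setGeneric("startStates", function(x) standardGeneric("startStates"))

#' @rdname startStates
#' @export
setMethod("startStates", "QEnvironment", function(x) x@startStates)

#' Corridor penalty accessor
#'
#' @param x a \linkS4class{LinearPath}.
#' @return numeric penalty.
#' @export
setGeneric("pathPenalty", function(x) standardGeneric("pathPenalty"))

#' @rdname pathPenalty
#' @export
setMethod("pathPenalty", "LinearPath", function(x) x@penalty)

#' Ordered voxel coordinates of a result
#'
#' @param x a \linkS4class{TrajectoryResult} or \linkS4class{LinearPath}.
#' @return integer matrix of ordered voxel coordinates.
#' @export
setGeneric("pathCoords", function(x) standardGeneric("pathCoords"))

#' @rdname pathCoords
#' @export
setMethod("pathCoords", "TrajectoryResult", function(x) x@path)

#' @rdname pathCoords
#' @export
setMethod("pathCoords", "LinearPath", function(x) x@centerLine)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object)
  cat(sprintf("VoxelVolume %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  rng <- range(object@data)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object)
  ids <- sort(unique(as.integer(object@labels)))
  ids <- ids[ids != 0L]
  cat(sprintf("LabelMap %d x %d x %d, %d structure label(s): %s\n",
              d[1], d[2], d[3], length(ids),
              paste(ids, collapse = ", ")))
})

setMethod("show", "StructureCatalog", function(object) {
  df <- object@structures
  cat(sprintf("StructureCatalog with %d structures (goal id %d)\n",
              nrow(df), goalId(object)))
  print(df, row.names = FALSE)
})

setMethod("show", "LinearPath", function(object) {
  cat(sprintf(
    "LinearPath n=%d face=%s (u=%d, v=%d): %d center-line voxels, %d corridor voxels, penalty %.4g\n",
    object@n, object@face, object@u, object@v, object@lengthVoxels,
    nrow(object@corridor), object@penalty))
})

setMethod("show", "QEnvironment", function(object) {
  cat(sprintf("QEnvironment %d x %d x %d: %d nodes, %d terminal, %d start state(s)\n",
              object@dims[1], object@dims[2], object@dims[3],
              sum(object@admissible), sum(object@terminal),
              nrow(object@startStates)))
})

setMethod("show", "QTable", function(object) {
  cat(sprintf("QTable: %d nodes x 26 actions; value range [%.4g, %.4g]\n",
              nrow(object@q), min(object@q), max(object@q)))
})

setMethod("show", "TrajectoryResult", function(object) {
  cat(sprintf("TrajectoryResult: %d voxels from (%s), return %.4f, cause '%s'\n",
              nrow(object@path), paste(object@start, collapse = ", "),
              object@totalReturn, object@cause))
})
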
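#' Write a trajectory to JSON
#'
#' Serializes a Stage-1 \linkS4class{LinearPath} or a Stage-2
#' \linkS4class{TrajectoryResult} as ordered 1-based (row, col, slice)
#' triples with per-node labels and the path's total penalty or return.
#' The round trip through [readTrajectory()] is lossless.
#'
#' @param x a \linkS4class{LinearPath} or \linkS4class{TrajectoryResult}.
#' @param path output JSON path.
#' @param labelmap optional \linkS4class{LabelMap} supplying per-node labels.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(x, path, labelmap = NULL) {
  coords <- pathCoords(x)
  if (nrow(coords) == 0L) stop("empty path")
  labs <- rep(0L, nrow(coords))
  if (!is.null(labelmap)) labs <- as.integer(labels3d(labelmap)[coords])
  doc <- list(indexing = "1-based",
              coords = unname(apply(coords, 1, as.integer, simplify = FALSE)),
              labels = labs)
  if (is(x, "LinearPath")) {
    doc$type <- "linear"
    doc$penalty <- x@penalty
    doc$n <- x@n
    doc$face <- x@face
  } else {
    doc$type <- "qlearning"
    doc$total_return <- x@totalReturn
    doc$cause <- x@cause
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a trajectory JSON file
#'
#' @param path a file written by [writeTrajectory()].
#' @return list with \code{coords} (k x 3 integer matrix), \code{labels},
#'   \code{type} and the stored penalty or return.
#' @export
readTrajectory <- function(path) {
  doc <- jsonlite::fromJSON(path)
  cm <- doc$coords
  if (is.list(cm)) cm <- do.call(rbind, cm)
  doc$coords <- matrix(as.integer(cm), ncol = 3)
  doc$labels <- as.integer(doc$labels)
  doc
}

#' Burn a voxel set into a volume copy as an overlay
#'
#' Writes a copy of the volume in which the given voxels are set to a
#' sentinel intensity (the volume maximum plus a margin), so the path shows
#' up in any viewer or neuronavigation software, as NIfTI or as a derived
#' DICOM series with fresh instance identifiers.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param voxels integer matrix (k x 3) of voxels to burn (may be empty).
#' @param out output path (NIfTI) or directory (DICOM).
#' @param format "nifti" or "dicom".
#' @return \code{out}, invisibly.
#' @export
burnOverlay <- function(volume, voxels, out, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  d <- dim(volume)
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (nrow(voxels) > 0L) {
    if (any(voxels < 1L) || any(voxels[, 1] > d[1]) ||
        any(voxels[, 2] > d[2]) || any(voxels[, 3] > d[3]))
      stop("overlay voxel out of bounds")
  }
  data <- intensities(volume)
  rng <- range(data)
  sentinel <- rng[2] + max(1, 0.25 * (rng[2] - rng[1]))
  data[voxels] <- sentinel
  ov <- VoxelVolume(data, spacing(volume))
  if (format == "nifti") writeNiftiVolume(ov, out) else writeDicomSeries(ov, out)
  invisible(out)
}
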
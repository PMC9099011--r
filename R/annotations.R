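# Slice-wise polygon annotations (labelme-style JSON) -> integer label maps.
#
# Fill convention: a voxel belongs to a polygon when its pixel center lies
# strictly inside under the even-odd rule. With 1-based voxel indices the
# center of voxel (i, j) sits at (i - 0.5, j - 0.5) in the continuous
# corner-origin plane the polygon vertices live in. Boundary-touching
# centers are excluded. Overlaps resolve to the higher-penalty structure
# (ties to the higher id), which is the conservative choice for safety
# scoring.

#' Read annotation documents
#'
#' Accepts labelme-style JSON: \code{shapes[].label} and
#' \code{shapes[].points} as (x, y) = (col, row) vertex pairs, which are
#' transposed to (row, col) on read. The slice is taken from an explicit
#' 1-based \code{slice_index} field when present, else from the trailing
#' integer of \code{imagePath} (interpreted as a 0-based stack number).
#'
#' @param paths character vector of JSON file paths.
#' @return list of annotation documents, each
#'   \code{list(slice_index, shapes = list(list(label, points)))} with
#'   \code{points} an n x 2 (row, col) matrix.
#' @export
readAnnotations <- function(paths) {
  lapply(paths, function(p) {
    doc <- jsonlite::fromJSON(p, simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
    if (!is.null(doc$slice_index)) {
      si <- as.integer(doc$slice_index)
    } else if (!is.null(doc$imagePath)) {
      m <- regmatches(doc$imagePath,
                      regexpr("[0-9]+(?=\\.[A-Za-z]+$)", doc$imagePath,
                              perl = TRUE))
      if (!length(m)) stop("cannot derive slice index from imagePath in ", p)
      si <- as.integer(m) + 1L
    } else stop("annotation document lacks slice_index and imagePath: ", p)
    shapes <- lapply(doc$shapes, function(sh) {
      pts <- do.call(rbind, lapply(sh$points, as.numeric))
      if (is.null(pts) || nrow(pts) < 3L)
        stop("polygon with fewer than 3 vertices in ", p)
      list(label = sh$label, points = pts[, c(2, 1), drop = FALSE])
    })
    list(slice_index = si, shapes = shapes)
  })
}

# Even-odd (ray crossing) point-in-polygon, vectorized over points.
# Points strictly on an edge follow the half-open crossing convention.
.pointsInPolygon <- function(pr, pc, vr, vc) {
  nv <- length(vr)
  inside <- logical(length(pr))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Voxels (1-based row, col) of one polygon on one slice.
.fillPolygon <- function(points, dims) {
  r0 <- max(1L, floor(min(points[, 1]) + 0.5))
  r1 <- min(dims[1], ceiling(max(points[, 1]) + 0.5))
  c0 <- max(1L, floor(min(points[, 2]) + 0.5))
  c1 <- min(dims[2], ceiling(max(points[, 2]) + 0.5))
  if (r0 > r1 || c0 > c1) return(matrix(integer(0), 0, 2))
  g <- expand.grid(r = r0:r1, c = c0:c1)
  keep <- .pointsInPolygon(g$r - 0.5, g$c - 0.5, points[, 1], points[, 2])
  as.matrix(g[keep, , drop = FALSE])
}

#' Rasterize polygon annotations into a LabelMap
#'
#' Each polygon is filled on its slice with its structure's id under the
#' pixel-center-inside / even-odd rule; voxels covered by no polygon stay
#' 0. Overlapping polygons resolve to the higher-penalty structure, ties
#' to the higher id.
#'
#' @param docs annotation documents (see [readAnnotations()]).
#' @param dims integer(3) volume dimensions.
#' @param catalog a \linkS4class{StructureCatalog}; shape labels must
#'   resolve to catalog structure names.
#' @return A \linkS4class{LabelMap}.
#' @export
rasterizeAnnotations <- function(docs, dims, catalog) {
  dims <- as.integer(dims)
  df <- structures(catalog)
  lab <- array(0L, dim = dims)
  pen <- array(-1, dim = dims)   # assigned-structure penalty, -1 = none
  for (doc in docs) {
    si <- doc$slice_index
    if (is.na(si) || si < 1L || si > dims[3])
      stop("annotation slice index ", si, " outside volume Z range 1..", dims[3])
    for (sh in doc$shapes) {
      hit <- match(sh$label, df$name)
      if (is.na(hit)) stop("unknown label name: '", sh$label, "'")
      id <- df$id[hit]
      p <- df$penalty[hit]
      vox <- .fillPolygon(sh$points, dims)
      if (nrow(vox) == 0L) next
      idx <- cbind(vox, si)
      take <- (p > pen[idx]) | (p == pen[idx] & id > lab[idx])
      idx <- idx[take, , drop = FALSE]
      lab[idx] <- id
      pen[idx] <- p
    }
  }
  LabelMap(lab)
}
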
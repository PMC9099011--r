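# Stage 1: exhaustive entry-window enumeration on the six volume faces,
# straight-corridor tracing to the tumor, penalty scoring against labeled
# anatomy, and a staged reduction funnel to the top-l linear paths.

.faces <- c("x_min", "x_max", "y_min", "y_max", "z_min", "z_max")

# In-face axes per face: the window offsets (u, v) move along these two
# volume axes; the third axis is fixed at the face.
.faceAxes <- list(
  x_min = c(2L, 3L), x_max = c(2L, 3L),
  y_min = c(1L, 3L), y_max = c(1L, 3L),
  z_min = c(1L, 2L), z_max = c(1L, 2L))

#' Enumerate all candidate entry windows
#'
#' Divides each of the six volume faces into n x n windows at unit stride
#' with offsets u in [1, U - n] and v in [1, V - n], where (U, V) are the
#' two in-face dimensions. The total count has the closed form
#' 2(X-n)(Y-n) + 2(X-n)(Z-n) + 2(Y-n)(Z-n); faces too small for a window
#' contribute zero. Rows are ordered by (face, u, v).
#'
#' @param dims integer(3) volume dimensions (rows, cols, slices).
#' @param n window side length in voxels (the cell dimension).
#' @return data.frame with columns face, u, v, n; one row per window.
#' @examples
#' nrow(enumerateEntryWindows(c(8, 8, 4), 2))  # 120
#' @export
enumerateEntryWindows <- function(dims, n) {
  dims <- as.integer(dims)
  n <- as.integer(n)
  if (n < 1L) stop("cell dimension must be >= 1")
  parts <- lapply(.faces, function(f) {
    ax <- .faceAxes[[f]]
    U <- dims[ax[1]] - n
    V <- dims[ax[2]] - n
    if (U < 1L || V < 1L) return(NULL)
    g <- expand.grid(v = seq_len(V), u = seq_len(U))
    data.frame(face = f, u = g$u, v = g$v, n = n)
  })
  out <- do.call(rbind, parts)
  if (is.null(out) || nrow(out) == 0L)
    stop("cell dimension ", n, " admits no windows on any face of ",
         paste(dims, collapse = "x"))
  rownames(out) <- NULL
  out
}

#' Convert an entry area to a cell dimension
#'
#' @param areaCm2 entry area in cm^2 (e.g. the 1.5 cm^2 default aperture).
#' @param spacing voxel spacing in mm; the in-plane size is the geometric
#'   mean of the first two components.
#' @return integer window side length n.
#' @export
cellDimFromArea <- function(areaCm2, spacing) {
  inplane <- sqrt(spacing[1] * spacing[2])
  n <- as.integer(round(sqrt(areaCm2 * 100) / inplane))
  max(1L, n)
}

#' Face-center voxels of entry windows
#'
#' @param windows data.frame from [enumerateEntryWindows()].
#' @param dims integer(3) volume dimensions.
#' @return integer matrix (k x 3) of the windows' center voxels on their
#'   faces.
#' @export
windowCenters <- function(windows, dims) {
  dims <- as.integer(dims)
  k <- nrow(windows)
  out <- matrix(0L, k, 3)
  half <- windows$n %/% 2L
  for (f in .faces) {
    sel <- windows$face == f
    if (!any(sel)) next
    ax <- .faceAxes[[f]]
    fixedAx <- setdiff(1:3, ax)
    fixedVal <- if (grepl("min$", f)) 1L else dims[fixedAx]
    out[sel, fixedAx] <- fixedVal
    out[sel, ax[1]] <- windows$u[sel] + half[sel]
    out[sel, ax[2]] <- windows$v[sel] + half[sel]
  }
  out
}

#' Select the goal point for an entry window
#'
#' The corridor aims at the tumor voxel nearest (Euclidean, voxel units)
#' the window's face-center voxel, so each corridor stops at the proximal
#' tumor boundary; ties break to the lexicographically smallest
#' (row, col, slice).
#'
#' @param goal a \linkS4class{GoalRegion}.
#' @param point integer(3) window face-center voxel (or any coordinate).
#' @return integer(3) tumor voxel.
#' @export
selectGoalPoint <- function(goal, point) {
  vox <- goal@voxels
  if (nrow(vox) == 0L) stop("empty tumor region")
  d2 <- (vox[, 1] - point[1])^2 + (vox[, 2] - point[2])^2 +
        (vox[, 3] - point[3])^2
  as.integer(vox[which.min(d2), ])
}

#' Voxelize the straight segment between two voxels
#'
#' Parametric boundary-crossing traversal of the segment joining the two
#' voxel centers; includes both endpoints, consecutive voxels are
#' 26-adjacent, and exact corner hits resolve toward the positive axis.
#'
#' @param start,goal integer(3) voxel coordinates.
#' @param dims optional integer(3) bounds to validate against.
#' @return integer matrix (L x 3) of ordered voxels.
#' @export
traceCenterLine <- function(start, goal, dims = NULL) {
  start <- as.integer(start); goal <- as.integer(goal)
  if (!is.null(dims)) {
    if (any(start < 1L) || any(start > dims) || any(goal < 1L) ||
        any(goal > dims))
      stop("coordinates out of bounds")
  }
  cpp_trace_line(start, goal)
}

#' Sweep a corridor cross-section along a center line
#'
#' Prism: the union over center-line voxels of the n x n axis-aligned
#' window parallel to the entry face, centered on the voxel. Cylinder:
#' in-face offsets within radius n/2. Out-of-volume voxels are clipped;
#' the result is deduplicated.
#'
#' @param centerLine ordered voxel matrix (L x 3).
#' @param n cell dimension.
#' @param face entry face name.
#' @param shape "prism" or "cylinder".
#' @param dims integer(3) volume dimensions.
#' @return integer matrix (m x 3) of corridor voxels.
#' @export
sweepCorridor <- function(centerLine, n, face, shape = "prism", dims) {
  stopifnot(nrow(centerLine) >= 1L)
  n <- as.integer(n)
  off <- seq_len(n) - 1L - n %/% 2L
  g <- expand.grid(o1 = off, o2 = off)
  if (shape == "cylinder") g <- g[g$o1^2 + g$o2^2 <= (n / 2)^2, , drop = FALSE]
  ax <- .faceAxes[[face]]
  K <- nrow(g); L <- nrow(centerLine)
  out <- centerLine[rep(seq_len(L), each = K), , drop = FALSE]
  out[, ax[1]] <- out[, ax[1]] + rep(g$o1, times = L)
  out[, ax[2]] <- out[, ax[2]] + rep(g$o2, times = L)
  keep <- out[, 1] >= 1L & out[, 1] <= dims[1] &
          out[, 2] >= 1L & out[, 2] <= dims[2] &
          out[, 3] >= 1L & out[, 3] <= dims[3]
  out <- out[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  unique(out)
}

#' Penalty score of a corridor
#'
#' Sums, over corridor voxels inside the head mask that carry a nonzero
#' non-goal label, the labeled structure's catalog penalty; each
#' intersecting voxel adds the full structure penalty. Goal-label,
#' background and extracranial voxels contribute 0.
#'
#' @param corridor voxel matrix (m x 3).
#' @param labelmap a \linkS4class{LabelMap}.
#' @param catalog a \linkS4class{StructureCatalog}.
#' @param mask optional logical head-mask array (default: all in-head).
#' @return non-negative penalty.
#' @export
scorePath <- function(corridor, labelmap, catalog, mask = NULL) {
  labs <- labels3d(labelmap)[corridor]
  inMask <- if (is.null(mask)) rep(TRUE, length(labs)) else mask[corridor]
  df <- structures(catalog)
  bad <- setdiff(unique(labs[labs > 0L]), df$id)
  if (length(bad))
    stop("corridor voxel labeled with uncatalogued id: ",
         paste(bad, collapse = ", "))
  lut <- penaltyLUT(catalog)
  sel <- labs > 0L & inMask
  sum(lut[labs[sel]])
}

# Score a set of candidate windows at a given stride (>=1: sampled center
# line; 0: full swept corridor). Returns penalty and center-line length.
.scoreCandidates <- function(entries, goals, stride, n, faces, labelmap,
                             lutc, mask, dims, shape) {
  if (stride >= 1) {
    res <- cpp_score_lines(entries, goals, as.integer(stride),
                           labels3d(labelmap), lutc, mask, dims)
    return(list(penalty = res$penalty, length = res$length))
  }
  k <- nrow(entries)
  pen <- numeric(k); len <- integer(k)
  labs <- labels3d(labelmap)
  lut <- lutc[-1]
  for (i in seq_len(k)) {
    line <- cpp_trace_line(entries[i, ], goals[i, ])
    corr <- sweepCorridor(line, n, faces[i], shape, dims)
    lv <- labs[corr]
    sel <- lv > 0L & mask[corr]
    pen[i] <- sum(lut[lv[sel]])
    len[i] <- nrow(line)
  }
  list(penalty = pen, length = len)
}

#' Staged reduction of entry windows to the top-l linear paths
#'
#' Four score-then-keep passes over the candidate windows. By default the
#' passes score the center line sampled at every 8th voxel, every 2nd
#' voxel, every voxel, and finally the full swept corridor, keeping the
#' configured stage sizes (default 400/80/40/20) after each pass with
#' penalties sorted ascending. Ties break by shorter center line, then by
#' (face, u, v). Each returned path carries its final-pass penalty and its
#' full corridor.
#'
#' @param windows data.frame from [enumerateEntryWindows()] (all same n).
#' @param goal a \linkS4class{GoalRegion}.
#' @param labelmap a \linkS4class{LabelMap}.
#' @param catalog a \linkS4class{StructureCatalog}.
#' @param mask optional logical head-mask array.
#' @param config a \linkS4class{PlannerConfig}.
#' @return list of \linkS4class{LinearPath}, sorted by (penalty, length,
#'   face, u, v); fewer than the final stage size if fewer windows exist.
#' @export
stagedReduction <- function(windows, goal, labelmap, catalog, mask = NULL,
                            config = plannerConfig()) {
  stopifnot(nrow(windows) >= 1L)
  dims <- dim(labelmap)
  n <- windows$n[1]
  if (any(windows$n != n)) stop("all windows must share one cell dimension")
  validateLabels(labelmap, catalog)
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  lutc <- c(0, penaltyLUT(catalog))
  entries <- windowCenters(windows, dims)
  goals <- goal@voxels[cpp_nearest_voxel(entries, goal@voxels), , drop = FALSE]
  storage.mode(goals) <- "integer"

  cand <- seq_len(nrow(windows))
  faceIdx <- match(windows$face, .faces)
  pen <- len <- NULL
  for (pass in 1:4) {
    res <- .scoreCandidates(entries[cand, , drop = FALSE],
                            goals[cand, , drop = FALSE],
                            config@stageSampling[pass], n,
                            windows$face[cand], labelmap, lutc, mask, dims,
                            config@corridorShape)
    ord <- order(res$penalty, res$length, faceIdx[cand], windows$u[cand],
                 windows$v[cand])
    keep <- ord[seq_len(min(config@stageSizes[pass], length(cand)))]
    pen <- res$penalty[keep]
    len <- res$length[keep]
    cand <- cand[keep]
  }

  lapply(seq_along(cand), function(j) {
    i <- cand[j]
    line <- cpp_trace_line(entries[i, ], goals[i, ])
    corr <- sweepCorridor(line, n, windows$face[i], config@corridorShape,
                          dims)
    new("LinearPath", face = windows$face[i], u = as.integer(windows$u[i]),
        v = as.integer(windows$v[i]), n = as.integer(n),
        entry = as.integer(entries[i, ]), goalPoint = as.integer(goals[i, ]),
        centerLine = line, corridor = corr, penalty = pen[j],
        lengthVoxels = nrow(line))
  })
}
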
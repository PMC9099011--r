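# Synthetic labeled-head phantom: an ellipsoidal head containing one
# spherical tumor (the goal), tubular vessel-like structures and
# sheet-like tract structures, each with a catalog penalty, plus class-mean
# intensities with Gaussian noise. Every structure draws from its own
# child seed so adding one structure type never perturbs the others.

#' Construct a PhantomSpec
#'
#' Defaults describe a head-like test volume: an ellipsoid filling ~84% of
#' each axis, a deep spherical tumor slightly lateral of center, six
#' vessels of radius 2 alternating artery/vein labels, and two oblique
#' tract sheets of thickness 3. Intensity means (background 0, tissue 400,
#' tumor 700, vessel 800, tract 500; noise sd 20) give a clear head/air
#' threshold.
#'
#' @param dims integer(3) volume dimensions (min 16 x 16 x 8).
#' @param seed integer master seed.
#' @param headSemiAxes ellipsoid semi-axes in voxels.
#' @param tumorCenter,tumorRadius tumor sphere in voxels.
#' @param nVessels,vesselRadius,vesselWaypoints vessel polylines.
#' @param nTracts,tractThickness tract sheets.
#' @param intensities named numeric class means.
#' @param noiseSd additive Gaussian noise sd.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(dims = c(128L, 128L, 64L), seed = 1L,
                        headSemiAxes = 0.42 * dims,
                        tumorCenter = c(0.55, 0.5, 0.5) * dims,
                        tumorRadius = 0.08 * min(dims),
                        nVessels = 6L, vesselRadius = 2,
                        vesselWaypoints = 5L,
                        nTracts = 2L, tractThickness = 3,
                        intensities = c(background = 0, tissue = 400,
                                        tumor = 700, vessel = 800,
                                        tract = 500),
                        noiseSd = 20) {
  new("PhantomSpec", dims = as.integer(dims), seed = as.integer(seed),
      headSemiAxes = headSemiAxes, tumorCenter = tumorCenter,
      tumorRadius = tumorRadius, nVessels = as.integer(nVessels),
      vesselRadius = vesselRadius,
      vesselWaypoints = as.integer(vesselWaypoints),
      nTracts = as.integer(nTracts), tractThickness = tractThickness,
      intensities = intensities, noiseSd = noiseSd)
}

# axis-indexed arrays built by recycling along the flat order
.axisArrays <- function(d) {
  list(r = rep(seq_len(d[1]), times = d[2] * d[3]),
       c = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
       s = rep(seq_len(d[3]), each = d[1] * d[2]))
}

# Centripetal-free (uniform) Catmull-Rom interpolation through waypoints.
.catmullRom <- function(wp, samplesPerSeg = 200L) {
  n <- nrow(wp)
  P <- rbind(wp[1, ], wp, wp[n, ])
  out <- list()
  t <- seq(0, 1, length.out = samplesPerSeg)
  for (i in seq_len(n - 1L)) {
    p0 <- P[i, ]; p1 <- P[i + 1L, ]; p2 <- P[i + 2L, ]; p3 <- P[i + 3L, ]
    t2 <- t * t; t3 <- t2 * t
    seg <- outer(rep(1, length(t)), p1) +
      outer(t, 0.5 * (p2 - p0)) +
      outer(t2, 0.5 * (2 * p0 - 5 * p1 + 4 * p2 - p3)) +
      outer(t3, 0.5 * (-p0 + 3 * p1 - 3 * p2 + p3))
    out[[i]] <- seg
  }
  do.call(rbind, out)
}

.ballOffsets <- function(r) {
  R <- ceiling(r)
  g <- as.matrix(expand.grid(-R:R, -R:R, -R:R))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

# random point inside the head ellipsoid (rejection sampling)
.insideHead <- function(ctr, semi, margin = 0.85) {
  repeat {
    p <- ctr + semi * margin * stats::runif(3, -1, 1)
    if (sum(((p - ctr) / semi)^2) <= margin^2) return(p)
  }
}

#' Generate a synthetic labeled head phantom
#'
#' Deterministic given the spec's seed. Labels are painted in increasing
#' penalty order with the tumor last, so overlaps resolve exactly as the
#' rasterizer's higher-penalty-wins rule; all labeled voxels lie inside
#' the head mask.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{volume} (\linkS4class{VoxelVolume}),
#'   \code{labels} (\linkS4class{LabelMap}), \code{catalog}
#'   (\linkS4class{StructureCatalog}) and \code{headMask} (logical array).
#' @examples
#' ph <- generatePhantom(phantomSpec(dims = c(32, 32, 16)))
#' ph$catalog
#' @export
generatePhantom <- function(spec) {
  d <- spec@dims
  ax <- .axisArrays(d)
  ctr <- (d + 1) / 2
  semi <- spec@headSemiAxes
  ell <- ((ax$r - ctr[1]) / semi[1])^2 + ((ax$c - ctr[2]) / semi[2])^2 +
         ((ax$s - ctr[3]) / semi[3])^2
  head <- array(ell <= 1, dim = d)

  catalog <- StructureCatalog(data.frame(
    id = 1:4,
    name = c("tumor", "artery", "vein", "tract"),
    category = c("tumor", "artery", "vein", "tract"),
    penalty = c(0, 100, 40, 80),
    is_goal = c(TRUE, FALSE, FALSE, FALSE)))

  labels <- array(0L, dim = d)

  paintVessel <- function(i) {
    set.seed(spec@seed * 1000L + i)           # child seed per structure
    wp <- do.call(rbind, lapply(seq_len(spec@vesselWaypoints),
                                function(j) .insideHead(ctr, semi)))
    pts <- unique(round(.catmullRom(wp)))
    off <- .ballOffsets(spec@vesselRadius)
    vox <- pts[rep(seq_len(nrow(pts)), each = nrow(off)), , drop = FALSE] +
           off[rep(seq_len(nrow(off)), times = nrow(pts)), , drop = FALSE]
    vox <- unique(vox)
    keep <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
            vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
    vox <- vox[keep, , drop = FALSE]
    storage.mode(vox) <- "integer"
    keep <- head[vox]
    vox[keep, , drop = FALSE]
  }

  # paint in increasing penalty: veins (40), tracts (80), arteries (100)
  veinIdx <- seq_len(spec@nVessels)[seq_len(spec@nVessels) %% 2L == 0L]
  artIdx <- setdiff(seq_len(spec@nVessels), veinIdx)
  for (i in veinIdx) labels[paintVessel(i)] <- 3L

  if (spec@nTracts > 0L) {
    for (i in seq_len(spec@nTracts)) {
      set.seed(spec@seed * 2000L + i)
      nrm <- stats::rnorm(3)
      nrm <- nrm / sqrt(sum(nrm^2))
      p0 <- .insideHead(ctr, semi, margin = 0.5)
      dot <- (ax$r - p0[1]) * nrm[1] + (ax$c - p0[2]) * nrm[2] +
             (ax$s - p0[3]) * nrm[3]
      sheet <- array(abs(dot) <= spec@tractThickness / 2, dim = d) & head
      labels[sheet] <- 4L
    }
  }

  for (i in artIdx) labels[paintVessel(i)] <- 2L

  tum <- ((ax$r - spec@tumorCenter[1])^2 + (ax$c - spec@tumorCenter[2])^2 +
          (ax$s - spec@tumorCenter[3])^2) <= spec@tumorRadius^2
  tum <- array(tum, dim = d) & head
  labels[tum] <- 1L

  means <- spec@intensities
  img <- array(means["background"], dim = d)
  img[head] <- means["tissue"]
  img[labels == 4L] <- means["tract"]
  img[labels == 2L | labels == 3L] <- means["vessel"]
  img[labels == 1L] <- means["tumor"]
  set.seed(spec@seed * 3000L + 1L)
  img <- img + array(stats::rnorm(prod(d), 0, spec@noiseSd), dim = d)

  list(volume = VoxelVolume(img), labels = LabelMap(labels),
       catalog = catalog, headMask = head)
}

#' Generate an analytic corridor micro-world
#'
#' A box environment with a straight corridor of the given width running
#' the length of the slice axis, walled by hazard nodes, with a single
#' goal voxel centered on the far face and start states spanning the near
#' corridor face. The metadata records the closed-form optimal discounted
#' return per start (a geometric series over the Chebyshev-optimal move
#' count), independently of any value-iteration run.
#'
#' @param length number of corridor slices before the goal slice (>= 3).
#' @param width corridor cross-section side (>= 1).
#' @param hazardPenalty penalty magnitude of wall nodes; walls are
#'   terminal when positive, ordinary step-cost nodes when 0.
#' @param goalReward reward on entering the goal voxel.
#' @param stepCost reward on entering an ordinary node.
#' @param gamma discount used for the metadata returns.
#' @return list with \code{env} (a \linkS4class{QEnvironment}) and
#'   \code{metadata} (optimal return per start, the unique optimal path
#'   when one exists, and a tie flag).
#' @export
generateCorridorWorld <- function(length, width = 1L, hazardPenalty = 50,
                                  goalReward = 100, stepCost = -1,
                                  gamma = 0.9) {
  stopifnot(length >= 3L, width >= 1L)
  d <- as.integer(c(width + 2L, width + 2L, length + 1L))
  adm <- array(TRUE, dim = d)
  reward <- array(stepCost, dim = d)
  terminal <- array(FALSE, dim = d)

  corrIdx <- 2:(width + 1L)
  inCorr <- array(FALSE, dim = d)
  inCorr[corrIdx, corrIdx, seq_len(length)] <- TRUE
  gctr <- 1L + as.integer(ceiling(width / 2))
  goalVox <- c(gctr, gctr, length + 1L)

  hazard <- !inCorr
  hazard[goalVox[1], goalVox[2], goalVox[3]] <- FALSE
  if (hazardPenalty > 0) {
    reward[hazard] <- -hazardPenalty
    terminal[hazard] <- TRUE
  }
  reward[goalVox[1], goalVox[2], goalVox[3]] <- goalReward
  terminal[goalVox[1], goalVox[2], goalVox[3]] <- TRUE

  starts <- as.matrix(expand.grid(row = corrIdx, col = corrIdx, slice = 1L))
  starts <- starts[order(starts[, 1], starts[, 2]), , drop = FALSE]
  dimnames(starts) <- NULL
  storage.mode(starts) <- "integer"
  env <- new("QEnvironment", dims = d, admissible = adm, reward = reward,
             terminal = terminal, startStates = starts)

  closedForm <- function(k) {
    # k moves: k-1 step costs then the discounted goal reward
    if (k == 1L) return(goalReward)
    stepCost * (1 - gamma^(k - 1)) / (1 - gamma) + gamma^(k - 1) * goalReward
  }
  moves <- pmax(abs(starts[, 1] - goalVox[1]), abs(starts[, 2] - goalVox[2]),
                abs(starts[, 3] - goalVox[3]))
  rets <- vapply(moves, closedForm, 0)
  unique_path <- NULL
  ties <- !(width == 1L && hazardPenalty > 0)
  if (!ties)
    unique_path <- cbind(rep(2L, length + 1L), rep(2L, length + 1L),
                         seq_len(length + 1L))
  list(env = env,
       metadata = list(goal = goalVox, optimalReturns = rets,
                       optimalMoves = moves, ties = ties,
                       optimalPath = unique_path, gamma = gamma,
                       goalReward = goalReward, stepCost = stepCost,
                       hazardPenalty = hazardPenalty))
}
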
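#' @useDynLib CorticoPath, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.categories <- c("artery", "vein", "sinus", "tract", "eloquent_cortex",
                 "nucleus", "tumor", "other")

#' VoxelVolume: a 3D scalar intensity grid with physical spacing
#'
#' The planning space: a 3D grid of scalar intensities, addressed by 1-based
#' \code{(row, column, slice)} triples, with millimetre spacing per axis.
#' Rows and columns are the in-plane matrix dimensions; the slice index runs
#' along the axial stack.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), voxel size in mm along (row, col, slice).
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3D array")
    if (any(d < 1L)) return("all dimensions must be >= 1")
    if (length(object@spacing) != 3L) return("spacing must have length 3")
    if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
      return("spacing must be positive and finite")
    TRUE
  })

#' Construct a VoxelVolume
#'
#' @param data 3D numeric array (rows x columns x slices).
#' @param spacing voxel spacing in mm along (row, col, slice).
#' @return A \linkS4class{VoxelVolume}.
#' @examples
#' v <- VoxelVolume(array(0, c(8, 8, 4)))
#' dim(v)
#' @export
VoxelVolume <- function(data, spacing = c(1, 1, 1)) {
  new("VoxelVolume", data = data, spacing = as.numeric(spacing))
}

#' LabelMap: integer structure labels aligned to a volume
#'
#' An integer grid of the same dimensions as its paired
#' \linkS4class{VoxelVolume}; 0 is background, every other value names a
#' structure in a \linkS4class{StructureCatalog}.
#'
#' @slot labels 3D integer array, 0 = background.
#' @export
setClass("LabelMap",
  representation(labels = "array"),
  validity = function(object) {
    d <- dim(object@labels)
    if (length(d) != 3L) return("labels must be a 3D array")
    lab <- object@labels
    if (any(lab < 0L)) return("labels must be non-negative")
    TRUE
  })

#' Construct a LabelMap
#'
#' @param labels 3D integer array of structure ids (0 = background).
#' @return A \linkS4class{LabelMap}.
#' @export
LabelMap <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels)
}

#' StructureCatalog: penalty and reward semantics of the label values
#'
#' Lists the labeled anatomical structures: surgical avoid-structures
#' (arteries, veins, dural sinuses, white-matter tracts, eloquent cortex,
#' deep nuclei) each carry a non-negative penalty accumulated when a
#' candidate corridor touches them, and exactly one structure -- the tumor
#' -- is the goal whose voxels are rewarded rather than penalized.
#'
#' @slot structures data.frame with columns \code{id} (positive integer),
#'   \code{name}, \code{category}, \code{penalty} (>= 0, ignored for the
#'   tumor) and \code{is_goal}.
#' @export
setClass("StructureCatalog",
  representation(structures = "data.frame"),
  validity = function(object) {
    df <- object@structures
    need <- c("id", "name", "category", "penalty", "is_goal")
    if (!all(need %in% names(df)))
      return(paste("structures must have columns:", paste(need, collapse = ", ")))
    if (nrow(df) < 1L) return("catalog must contain at least one structure")
    if (anyDuplicated(df$id)) return("duplicate structure ids")
    if (any(df$id < 1L)) return("structure ids must be positive integers")
    if (!all(df$category %in% .categories))
      return(paste("unknown category; must be one of:",
                   paste(.categories, collapse = ", ")))
    if (any(df$penalty < 0)) return("negative penalty")
    ng <- sum(df$is_goal)
    if (ng == 0L) return("no goal structure")
    if (ng > 1L) return("multiple goal structures")
    if (df$category[df$is_goal] != "tumor")
      return("the goal structure must have category 'tumor'")
    TRUE
  })

#' Construct a StructureCatalog
#'
#' @param structures data.frame with columns id, name, category, penalty,
#'   is_goal.
#' @return A \linkS4class{StructureCatalog}.
#' @export
StructureCatalog <- function(structures) {
  structures$id <- as.integer(structures$id)
  structures$name <- as.character(structures$name)
  structures$category <- as.character(structures$category)
  structures$penalty <- as.numeric(structures$penalty)
  structures$is_goal <- as.logical(structures$is_goal)
  rownames(structures) <- NULL
  new("StructureCatalog", structures = structures)
}

#' GoalRegion: the tumor voxel set and its canonical target point
#'
#' @slot voxels integer matrix (k x 3) of tumor voxel coordinates.
#' @slot goalPoint integer(3), a canonical in-tumor target (the tumor voxel
#'   nearest its centroid); Stage-1 corridors aim at the per-window nearest
#'   tumor voxel instead, so they stop at the proximal tumor boundary.
#' @slot label integer, the tumor's catalog id.
#' @export
setClass("GoalRegion",
  representation(voxels = "matrix", goalPoint = "integer", label = "integer"),
  validity = function(object) {
    if (nrow(object@voxels) < 1L) return("empty tumor region")
    if (ncol(object@voxels) != 3L) return("voxels must be a k x 3 matrix")
    gp <- object@goalPoint
    if (length(gp) != 3L) return("goalPoint must have length 3")
    hit <- any(object@voxels[, 1] == gp[1] & object@voxels[, 2] == gp[2] &
               object@voxels[, 3] == gp[3])
    if (!hit) return("goalPoint must be one of the tumor voxels")
    TRUE
  })

#' LinearPath: a straight entry-window-to-tumor corridor (Stage 1 output)
#'
#' @slot face entry face, one of x_min, x_max, y_min, y_max, z_min, z_max.
#' @slot u,v 1-based window offsets in the two in-face axes.
#' @slot n window side length in voxels (the cell dimension).
#' @slot entry integer(3), the window's face-center voxel.
#' @slot goalPoint integer(3), the proximal tumor voxel the corridor aims at.
#' @slot centerLine ordered voxel coordinates (L x 3) of the segment
#'   voxelization; consecutive rows are 26-adjacent.
#' @slot corridor deduplicated voxel set (m x 3) of the swept cross-section,
#'   clipped to the volume.
#' @slot penalty accumulated structure penalty of the corridor.
#' @slot lengthVoxels number of center-line voxels.
#' @export
setClass("LinearPath",
  representation(face = "character", u = "integer", v = "integer",
                 n = "integer", entry = "integer", goalPoint = "integer",
                 centerLine = "matrix", corridor = "matrix",
                 penalty = "numeric", lengthVoxels = "integer"),
  validity = function(object) {
    if (object@penalty < 0) return("penalty must be >= 0")
    L <- nrow(object@centerLine)
    if (L < 1L) return("empty center line")
    if (!all(object@centerLine[1, ] == object@entry))
      return("center line must start at the window's entry voxel")
    if (!all(object@centerLine[L, ] == object@goalPoint))
      return("center line must end at the goal point")
    if (L > 1L) {
      step <- abs(diff(object@centerLine))
      if (any(step > 1L)) return("consecutive center-line voxels must be 26-adjacent")
    }
    TRUE
  })

#' PlannerConfig: Stage-1 funnel configuration
#'
#' @slot cellDims candidate window side lengths n (voxels).
#' @slot stageSizes keep-sizes of the four reduction passes (k1 > k2 > k3 > k4).
#' @slot stageSampling center-line sampling stride per pass; 0 means score
#'   the full swept corridor.
#' @slot entryAreaCm2 optional entry area (cm^2) convertible to n via the
#'   in-plane spacing.
#' @slot corridorShape "prism" or "cylinder".
#' @slot modeThreshold cell dimensions below this use entry-point mode in
#'   Stage 2; at or above it the corridors form the environment.
#' @slot seed integer seed for any randomized downstream step.
#' @export
setClass("PlannerConfig",
  representation(cellDims = "numeric", stageSizes = "numeric",
                 stageSampling = "numeric", entryAreaCm2 = "numeric",
                 corridorShape = "character", modeThreshold = "numeric",
                 seed = "integer"),
  validity = function(object) {
    ss <- object@stageSizes
    if (length(ss) != 4L) return("stageSizes must have length 4")
    if (any(ss <= 0) || any(diff(ss) >= 0))
      return("stage sizes must be positive and strictly decreasing")
    if (length(object@stageSampling) != 4L)
      return("stageSampling must have length 4")
    if (any(object@stageSampling < 0))
      return("stageSampling strides must be >= 0 (0 = full corridor)")
    if (!object@corridorShape %in% c("prism", "cylinder"))
      return("corridorShape must be 'prism' or 'cylinder'")
    if (any(object@cellDims < 1)) return("cell dimensions must be >= 1")
    TRUE
  })

#' Construct a PlannerConfig
#'
#' Defaults mirror the reference study conditions: cell dimensions
#' 16/32/40/64, a four-pass funnel keeping 400/80/40/20 candidates scored at
#' strides 8/2/1/full-corridor, a 1.5 cm^2 entry area, and entry-point mode
#' for cell dimensions below 40.
#'
#' @param cellDims window side lengths to plan at.
#' @param stageSizes four strictly decreasing keep-sizes.
#' @param stageSampling per-pass stride (0 = full swept corridor).
#' @param entryAreaCm2 entry area in cm^2 (used by [cellDimFromArea()]).
#' @param corridorShape "prism" or "cylinder".
#' @param modeThreshold Stage-2 mode cut on n.
#' @param seed integer seed.
#' @return A \linkS4class{PlannerConfig}.
#' @export
plannerConfig <- function(cellDims = c(16, 32, 40, 64),
                          stageSizes = c(400, 80, 40, 20),
                          stageSampling = c(8, 2, 1, 0),
                          entryAreaCm2 = 1.5,
                          corridorShape = "prism",
                          modeThreshold = 40,
                          seed = 42L) {
  new("PlannerConfig", cellDims = as.numeric(cellDims),
      stageSizes = as.numeric(stageSizes),
      stageSampling = as.numeric(stageSampling),
      entryAreaCm2 = as.numeric(entryAreaCm2),
      corridorShape = corridorShape,
      modeThreshold = as.numeric(modeThreshold),
      seed = as.integer(seed))
}

#' QEnvironment: the admissible node set the agent moves in
#'
#' Dense-array form of the Stage-2 environment: per-voxel admissibility,
#' entry reward and terminal flags over the bounding dims, plus the start
#' states (snapped entry-window centers).
#'
#' @slot dims integer(3) bounding dimensions.
#' @slot admissible logical array: TRUE where the agent may stand.
#' @slot reward numeric array: reward received on entering each voxel.
#' @slot terminal logical array: entering ends the episode.
#' @slot startStates integer matrix (k x 3) of start coordinates.
#' @export
setClass("QEnvironment",
  representation(dims = "integer", admissible = "array", reward = "array",
                 terminal = "array", startStates = "matrix"),
  validity = function(object) {
    d <- object@dims
    if (!all(dim(object@admissible) == d)) return("admissible dims mismatch")
    if (!all(dim(object@reward) == d)) return("reward dims mismatch")
    if (!all(dim(object@terminal) == d)) return("terminal dims mismatch")
    if (!any(object@admissible)) return("empty node set")
    if (any(!is.finite(object@reward[object@admissible])))
      return("rewards must be finite")
    ss <- object@startStates
    if (nrow(ss) < 1L) return("no start states")
    for (i in seq_len(nrow(ss))) {
      if (any(ss[i, ] < 1L) || any(ss[i, ] > d))
        return("start state out of bounds")
      if (!object@admissible[ss[i, 1], ss[i, 2], ss[i, 3]])
        return("start state outside the admissible node set")
    }
    TRUE
  })

#' QConfig: Q-learning hyperparameters
#'
#' @slot alpha learning rate in (0, 1].
#' @slot gamma discount factor in [0, 1).
#' @slot epsilon exploration probability.
#' @slot epsilonEnd final epsilon for linear decay (NA = constant epsilon).
#' @slot episodes number of training episodes.
#' @slot maxSteps per-episode step cap (NA = 4 x the Chebyshev diagonal of
#'   the environment's bounding box).
#' @slot goalReward reward on entering a tumor voxel.
#' @slot stepCost reward on entering an ordinary voxel (default -1).
#' @slot penaltyScale multiplier applied to catalog penalties.
#' @slot terminalOnHit whether entering a penalized structure ends the episode.
#' @slot startPolicy "starts" (uniform over start states) or "uniform"
#'   (uniform over all admissible nodes).
#' @slot seed integer RNG seed.
#' @export
setClass("QConfig",
  representation(alpha = "numeric", gamma = "numeric", epsilon = "numeric",
                 epsilonEnd = "numeric", episodes = "integer",
                 maxSteps = "integer", goalReward = "numeric",
                 stepCost = "numeric", penaltyScale = "numeric",
                 terminalOnHit = "logical", startPolicy = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@alpha <= 0 || object@alpha > 1) return("alpha must be in (0, 1]")
    if (object@gamma < 0 || object@gamma >= 1) return("gamma must be in [0, 1)")
    if (object@epsilon < 0 || object@epsilon > 1) return("epsilon must be in [0, 1]")
    if (object@episodes < 0L) return("episodes must be >= 0")
    if (object@goalReward <= 0) return("goalReward must be positive")
    if (!object@startPolicy %in% c("starts", "uniform"))
      return("startPolicy must be 'starts' or 'uniform'")
    TRUE
  })

#' Construct a QConfig
#'
#' The default episode count matches the reference study's training budget;
#' tests and examples scale it down. alpha defaults high (0.8) because
#' transitions on the voxel grid are deterministic, so each update is close
#' to an exact Bellman backup; gamma defaults to 0.99 so the discounted
#' tumor reward remains positive at realistic scalp-to-tumor depths.
#'
#' @param alpha learning rate in (0, 1].
#' @param gamma discount in [0, 1).
#' @param epsilon exploration probability (optionally decaying linearly to
#'   \code{epsilonEnd}).
#' @param epsilonEnd final epsilon (NA = constant).
#' @param episodes training episodes.
#' @param maxSteps per-episode cap (NA = 4 x Chebyshev diagonal).
#' @param goalReward tumor entry reward.
#' @param stepCost ordinary-node entry reward.
#' @param penaltyScale multiplier on catalog penalties.
#' @param terminalOnHit end episodes on structure contact.
#' @param startPolicy "starts" or "uniform".
#' @param seed integer seed.
#' @return A \linkS4class{QConfig}.
#' @export
qConfig <- function(alpha = 0.8, gamma = 0.99, epsilon = 0.1,
                    epsilonEnd = NA_real_, episodes = 500000L,
                    maxSteps = NA_integer_, goalReward = 100,
                    stepCost = -1, penaltyScale = 1,
                    terminalOnHit = TRUE, startPolicy = "starts",
                    seed = 42L) {
  new("QConfig", alpha = alpha, gamma = gamma, epsilon = epsilon,
      epsilonEnd = as.numeric(epsilonEnd), episodes = as.integer(episodes),
      maxSteps = as.integer(maxSteps), goalReward = goalReward,
      stepCost = stepCost, penaltyScale = penaltyScale,
      terminalOnHit = terminalOnHit, startPolicy = startPolicy,
      seed = as.integer(seed))
}

#' QTable: the state x action value table
#'
#' Values are kept as a dense (node x 26) matrix; \code{nodeIndex} maps each
#' admissible voxel to its row. Actions are indexed by the fixed enumeration
#' returned by [actionOffsets()].
#'
#' @slot dims integer(3) bounding dims.
#' @slot nodeIndex integer array mapping voxels to node rows (0 = not a node).
#' @slot nodeVoxels integer matrix (N x 3), row i = coordinates of node i.
#' @slot q numeric matrix (N x 26) of action values.
#' @export
setClass("QTable",
  representation(dims = "integer", nodeIndex = "array",
                 nodeVoxels = "matrix", q = "matrix"),
  validity = function(object) {
    if (ncol(object@q) != 26L) return("q must have 26 action columns")
    if (nrow(object@q) != nrow(object@nodeVoxels))
      return("q rows must match nodeVoxels rows")
    if (any(!is.finite(object@q))) return("q values must be finite")
    TRUE
  })

#' TrajectoryResult: an extracted nonlinear voxel path
#'
#' @slot path ordered voxel coordinates (k x 3).
#' @slot totalReturn discounted return accumulated along the path.
#' @slot cause termination cause: "terminal", "cycle", "dead_end" or
#'   "max_steps".
#' @slot start integer(3) start voxel.
#' @export
setClass("TrajectoryResult",
  representation(path = "matrix", totalReturn = "numeric",
                 cause = "character", start = "integer"),
  validity = function(object) {
    if (nrow(object@path) < 1L) return("empty path")
    if (ncol(object@path) != 3L) return("path must be k x 3")
    TRUE
  })

#' PhantomSpec: parameters of the synthetic labeled-head phantom
#'
#' @slot dims integer(3) volume dimensions.
#' @slot seed integer master seed (per-structure child seeds derive from it).
#' @slot headSemiAxes ellipsoid semi-axes in voxels.
#' @slot tumorCenter,tumorRadius tumor sphere (voxels).
#' @slot nVessels,vesselRadius,vesselWaypoints tubular vessel structures.
#' @slot nTracts,tractThickness sheet-like tract structures.
#' @slot intensities named numeric: background, tissue, tumor, vessel,
#'   tract class means.
#' @slot noiseSd additive Gaussian noise sd.
#' @export
setClass("PhantomSpec",
  representation(dims = "integer", seed = "integer", headSemiAxes = "numeric",
                 tumorCenter = "numeric", tumorRadius = "numeric",
                 nVessels = "integer", vesselRadius = "numeric",
                 vesselWaypoints = "integer", nTracts = "integer",
                 tractThickness = "numeric", intensities = "numeric",
                 noiseSd = "numeric"),
  validity = function(object) {
    d <- object@dims
    if (any(d < c(16L, 16L, 8L))) return("dims must be at least (16, 16, 8)")
    ctr <- (d + 1) / 2
    off <- abs(object@tumorCenter - ctr)
    # tumor sphere fully inside the head ellipsoid (conservative bound)
    frac <- (off + object@tumorRadius) / object@headSemiAxes
    if (sqrt(sum(frac^2)) > 1)
      return("tumor sphere must lie fully inside the head ellipsoid")
    TRUE
  })
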
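# Stage 2 environment construction: the trained agent moves on a
# 26-neighbor voxel-node graph. Narrow Stage-1 paths contribute their entry
# points as start states over the whole in-head node set ("entry-point
# mode"); wide paths contribute their swept corridors as the node set
# itself ("corridor mode").

#' The fixed 26-action offset enumeration
#'
#' Actions are the 26 unit offsets (8 in-plane neighbors plus 9 in each of
#' the adjacent slices), indexed lexicographically over (dr, dc, ds) in
#' \{-1, 0, 1\}^3 with the null offset excluded. All Q-tables and walkers
#' share this enumeration.
#'
#' @return integer matrix (26 x 3) of (dr, dc, ds) offsets.
#' @export
actionOffsets <- function() {
  g <- expand.grid(ds = -1:1, dc = -1:1, dr = -1:1)
  g <- g[!(g$dr == 0 & g$dc == 0 & g$ds == 0), ]
  m <- as.matrix(g[order(g$dr, g$dc, g$ds), c("dr", "dc", "ds")])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Populate node rewards and terminal flags of an environment
#'
#' Tumor-label nodes receive \code{+goalReward} and are terminal;
#' penalized-structure nodes receive \code{-penalty * penaltyScale} and are
#' terminal when \code{terminalOnHit}; every other admissible node carries
#' the unit step cost (the "1 penalty score" of ordinary nodes, expressed
#' as a reward of -1).
#'
#' @param env a \linkS4class{QEnvironment} (admissible set already built).
#' @param labelmap a \linkS4class{LabelMap}.
#' @param catalog a \linkS4class{StructureCatalog}.
#' @param config a \linkS4class{QConfig}.
#' @return the environment with \code{reward} and \code{terminal} populated.
#' @export
assignRewards <- function(env, labelmap, catalog, config = qConfig()) {
  d <- env@dims
  adm <- env@admissible
  labs <- labels3d(labelmap)
  inside <- unique(as.integer(labs[adm]))
  inside <- inside[inside != 0L]
  df <- structures(catalog)
  bad <- setdiff(inside, df$id)
  if (length(bad))
    stop("environment contains uncatalogued label(s): ",
         paste(bad, collapse = ", "))
  reward <- array(config@stepCost, dim = d)
  terminal <- array(FALSE, dim = d)
  gid <- goalId(catalog)
  for (i in seq_len(nrow(df))) {
    sel <- adm & labs == df$id[i]
    if (df$id[i] == gid) {
      reward[sel] <- config@goalReward
      terminal[sel] <- TRUE
    } else {
      reward[sel] <- -df$penalty[i] * config@penaltyScale
      terminal[sel] <- config@terminalOnHit
    }
  }
  reward[!adm] <- 0
  initialize(env, reward = reward, terminal = terminal)
}

# Snap coordinates to the nearest admissible voxel (Euclidean, ties to the
# lexicographically smallest). Entry-window centers sit on the volume
# faces, outside the head, so starts are projected onto the node set.
.snapToNodes <- function(points, admissible) {
  vox <- which(admissible, arr.ind = TRUE)
  colnames(vox) <- NULL
  vox <- vox[order(vox[, 1], vox[, 2], vox[, 3]), , drop = FALSE]
  storage.mode(vox) <- "integer"
  storage.mode(points) <- "integer"
  vox[cpp_nearest_voxel(points, vox), , drop = FALSE]
}

#' Build a Q-learning environment from Stage-1 linear paths
#'
#' Paths with cell dimension below \code{config@modeThreshold} run in
#' entry-point mode: the node set is the whole head mask and the paths
#' contribute start states. Paths at or above the threshold contribute
#' their swept corridors as the node set (intersected with the head mask).
#' A mixed list yields the corridor-union node set with every path's entry
#' center as a start state. All start states are snapped to the nearest
#' admissible node.
#'
#' @param paths list of \linkS4class{LinearPath}.
#' @param labelmap a \linkS4class{LabelMap}.
#' @param catalog a \linkS4class{StructureCatalog}.
#' @param mask logical head-mask array ("extracranial areas are excluded").
#' @param config a \linkS4class{PlannerConfig} (for the mode threshold).
#' @param qconfig a \linkS4class{QConfig} (for the reward scheme).
#' @return A \linkS4class{QEnvironment}.
#' @export
buildEnvironment <- function(paths, labelmap, catalog, mask,
                             config = plannerConfig(),
                             qconfig = qConfig()) {
  stopifnot(length(paths) >= 1L)
  d <- dim(labelmap)
  ns <- vapply(paths, function(p) p@n, 1L)
  wide <- ns >= config@modeThreshold
  if (any(wide)) {
    adm <- array(FALSE, dim = d)
    for (p in paths[wide]) adm[p@corridor] <- TRUE
    adm <- adm & mask
  } else {
    adm <- mask
  }
  if (!any(adm)) stop("empty node set")
  entries <- do.call(rbind, lapply(paths, function(p) p@entry))
  starts <- .snapToNodes(entries, adm)
  env <- new("QEnvironment", dims = as.integer(d), admissible = adm,
             reward = array(0, dim = d), terminal = array(FALSE, dim = d),
             startStates = starts)
  assignRewards(env, labelmap, catalog, qconfig)
}

#' Admissible neighbors of a node
#'
#' @param node integer(3) voxel coordinate; must be an environment node.
#' @param env a \linkS4class{QEnvironment}.
#' @return data.frame with columns \code{action} (index into
#'   [actionOffsets()]), \code{row}, \code{col}, \code{slice}; one row per
#'   in-bounds admissible neighbor (up to 26; the node itself never
#'   appears).
#' @export
neighbors <- function(node, env) {
  node <- as.integer(node)
  d <- env@dims
  if (any(node < 1L) || any(node > d) ||
      !env@admissible[node[1], node[2], node[3]])
    stop("node is not in the environment")
  off <- actionOffsets()
  nb <- sweep(off, 2, node, "+")
  ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
        nb[, 3] >= 1L & nb[, 3] <= d[3]
  ok[ok] <- env@admissible[nb[ok, , drop = FALSE]]
  data.frame(action = which(ok), row = nb[ok, 1], col = nb[ok, 2],
             slice = nb[ok, 3])
}
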
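# Tabular Q-learning (Stage 2): the temporal-difference update, episode
# rollouts, seeded training via the compiled core, and greedy path
# extraction from the trained table.

#' The tabular Q-learning value update
#'
#' \code{newQ = q_sa + alpha * (reward + gamma * maxFuture - q_sa)}: the
#' old value moves toward the bootstrapped target formed by the entry
#' reward of the destination plus the discounted best future value.
#'
#' @param q_sa current Q(state, action) value.
#' @param reward reward received on entering the destination node.
#' @param maxFuture max over actions of Q(destination, .) (0 for terminal
#'   destinations).
#' @param alpha learning rate in (0, 1].
#' @param gamma discount factor in [0, 1).
#' @return the updated value.
#' @examples
#' qUpdate(0, 10, 0, alpha = 0.5, gamma = 0.9)  # 5
#' @export
qUpdate <- function(q_sa, reward, maxFuture, alpha, gamma) {
  q_sa + alpha * (reward + gamma * maxFuture - q_sa)
}

# Dense node indexing shared by the table, trainer and oracle: node i is
# the i-th admissible voxel in column-major (flat) order.
.nodeIndexing <- function(env) {
  flat <- which(as.vector(env@admissible))
  nodeIndex <- array(0L, dim = env@dims)
  nodeIndex[flat] <- seq_along(flat)
  vox <- which(env@admissible, arr.ind = TRUE)
  colnames(vox) <- NULL
  storage.mode(vox) <- "integer"
  list(nodeIndex = nodeIndex, nodeVoxels = vox)
}

#' Create an all-zero Q-table for an environment
#'
#' @param env a \linkS4class{QEnvironment}.
#' @return A \linkS4class{QTable} with one row per admissible node and 26
#'   action columns (see [actionOffsets()]).
#' @export
qTable <- function(env) {
  ix <- .nodeIndexing(env)
  new("QTable", dims = env@dims, nodeIndex = ix$nodeIndex,
      nodeVoxels = ix$nodeVoxels,
      q = matrix(0, nrow = nrow(ix$nodeVoxels), ncol = 26L))
}

.defaultMaxSteps <- function(env) 4L * max(env@dims)

.epsSchedule <- function(config) {
  e1 <- if (is.na(config@epsilonEnd)) config@epsilon else config@epsilonEnd
  c(config@epsilon, e1)
}

#' Run one epsilon-greedy training episode
#'
#' Reference R implementation of a single episode: the start is drawn by
#' the configured policy, actions explore uniformly with probability
#' epsilon and otherwise exploit the argmax (ties to the lowest action
#' index), and the table is updated in place via [qUpdate()]. The episode
#' ends on entering a terminal node or after \code{maxSteps} steps.
#'
#' @param env a \linkS4class{QEnvironment}.
#' @param qtable a \linkS4class{QTable}.
#' @param config a \linkS4class{QConfig}.
#' @param start optional integer(3) start voxel (default: drawn by policy).
#' @return list with the updated \code{qtable}, the \code{trace} of
#'   visited voxels, the discounted \code{return} and the termination
#'   \code{cause} ("terminal" or "max_steps").
#' @export
runEpisode <- function(env, qtable, config = qConfig(), start = NULL) {
  off <- actionOffsets()
  maxSteps <- if (is.na(config@maxSteps)) .defaultMaxSteps(env) else config@maxSteps
  if (is.null(start)) {
    pool <- if (config@startPolicy == "uniform") qtable@nodeVoxels else env@startStates
    start <- pool[sample.int(nrow(pool), 1L), ]
  }
  cur <- as.integer(start)
  q <- qtable@q
  trace <- list(cur)
  ret <- 0; gpow <- 1
  cause <- "max_steps"
  for (step in seq_len(maxSteps)) {
    nb <- neighbors(cur, env)
    if (nrow(nb) == 0L) stop("state with zero admissible actions: ",
                             paste(cur, collapse = ","))
    ni <- qtable@nodeIndex[cur[1], cur[2], cur[3]]
    a <- if (stats::runif(1) < config@epsilon) {
      nb$action[sample.int(nrow(nb), 1L)]
    } else {
      nb$action[which.max(q[ni, nb$action])]
    }
    dest <- cur + off[a, ]
    r <- env@reward[dest[1], dest[2], dest[3]]
    ret <- ret + gpow * r
    gpow <- gpow * config@gamma
    term <- env@terminal[dest[1], dest[2], dest[3]]
    maxFuture <- 0
    if (!term) {
      nbd <- neighbors(dest, env)
      nj <- qtable@nodeIndex[dest[1], dest[2], dest[3]]
      if (nrow(nbd) > 0L) maxFuture <- max(q[nj, nbd$action])
    }
    q[ni, a] <- qUpdate(q[ni, a], r, maxFuture, config@alpha, config@gamma)
    trace[[length(trace) + 1L]] <- dest
    if (term) { cause <- "terminal"; break }
    cur <- dest
  }
  qtable@q <- q
  list(qtable = qtable, trace = do.call(rbind, trace), return = ret,
       cause = cause)
}

#' Train a Q-table on an environment
#'
#' Runs the configured number of epsilon-greedy episodes through the
#' compiled training loop under a single seeded random stream; identical
#' (environment, config, seed) yield bit-identical tables.
#'
#' @param env a \linkS4class{QEnvironment}.
#' @param config a \linkS4class{QConfig}.
#' @return list with \code{qtable} (a \linkS4class{QTable}) and
#'   \code{stats} (per-episode discounted return, step count and
#'   termination cause: "goal", "structure", "max_steps" or "dead_end").
#' @export
train <- function(env, config = qConfig()) {
  ix <- .nodeIndexing(env)
  q <- matrix(0, nrow = nrow(ix$nodeVoxels), ncol = 26L)
  eps <- .epsSchedule(config)
  maxSteps <- if (is.na(config@maxSteps)) .defaultMaxSteps(env) else config@maxSteps
  set.seed(config@seed)
  res <- cpp_train(as.integer(ix$nodeIndex), env@dims,
                   as.numeric(env@reward), as.integer(env@terminal),
                   env@startStates, ix$nodeVoxels, q,
                   config@episodes, config@alpha, config@gamma,
                   eps[1], eps[2], maxSteps,
                   config@startPolicy == "uniform")
  qt <- new("QTable", dims = env@dims, nodeIndex = ix$nodeIndex,
            nodeVoxels = ix$nodeVoxels, q = q)
  cause <- c("max_steps", "goal", "structure", "dead_end")[res$cause + 1L]
  list(qtable = qt,
       stats = data.frame(return = res$returns, steps = res$steps,
                          cause = cause))
}

#' Extract the greedy best path from a trained table
#'
#' Walks the argmax action (ties to the lowest action index) from the
#' start until a terminal node. Revisiting any node aborts with a cycle
#' diagnosis, and a node without admissible actions aborts as a dead end
#' -- both indicate an undertrained table.
#'
#' @param qtable a trained \linkS4class{QTable}.
#' @param env the \linkS4class{QEnvironment} it was trained on.
#' @param start integer(3) start voxel (an environment node).
#' @param gamma discount used for the reported return.
#' @return A \linkS4class{TrajectoryResult} with the ordered coordinates
#'   and the discounted return.
#' @export
extractBestPath <- function(qtable, env, start, gamma = qConfig()@gamma) {
  start <- as.integer(start)
  d <- env@dims
  if (any(start < 1L) || any(start > d) ||
      !env@admissible[start[1], start[2], start[3]])
    stop("start is not an environment node")
  if (env@terminal[start[1], start[2], start[3]])
    return(new("TrajectoryResult", path = matrix(start, 1, 3),
               totalReturn = env@reward[start[1], start[2], start[3]],
               cause = "terminal", start = start))
  off <- actionOffsets()
  visited <- new.env(hash = TRUE)
  key <- function(v) paste(v, collapse = ",")
  assign(key(start), TRUE, envir = visited)
  cur <- start
  path <- list(start)
  ret <- 0; gpow <- 1
  repeat {
    nb <- neighbors(cur, env)
    if (nrow(nb) == 0L) stop("dead-end node at ", key(cur))
    ni <- qtable@nodeIndex[cur[1], cur[2], cur[3]]
    a <- nb$action[which.max(qtable@q[ni, nb$action])]
    dest <- cur + off[a, ]
    ret <- ret + gpow * env@reward[dest[1], dest[2], dest[3]]
    gpow <- gpow * gamma
    path[[length(path) + 1L]] <- dest
    if (env@terminal[dest[1], dest[2], dest[3]]) break
    if (!is.null(visited[[key(dest)]]))
      stop("cycle detected before reaching a terminal node (undertrained Q-table)")
    assign(key(dest), TRUE, envir = visited)
    cur <- dest
  }
  new("TrajectoryResult", path = do.call(rbind, path), totalReturn = ret,
      cause = "terminal", start = start)
}

#' Rank start states by their greedy-path return
#'
#' @param qtable a trained \linkS4class{QTable}.
#' @param env the environment.
#' @param gamma discount used for the reported returns.
#' @return data.frame with start coordinates, the greedy discounted
#'   \code{return} (NA where extraction failed), a \code{failed} flag and
#'   the failure \code{reason}; sorted by return descending with failures
#'   last in input order. The extracted paths are attached as the
#'   \code{"paths"} attribute.
#' @export
rankStarts <- function(qtable, env, gamma = qConfig()@gamma) {
  ss <- env@startStates
  k <- nrow(ss)
  ret <- rep(NA_real_, k)
  reason <- rep(NA_character_, k)
  paths <- vector("list", k)
  for (i in seq_len(k)) {
    r <- tryCatch(extractBestPath(qtable, env, ss[i, ], gamma = gamma),
                  error = function(e) e)
    if (inherits(r, "error")) {
      reason[i] <- conditionMessage(r)
    } else {
      ret[i] <- r@totalReturn
      paths[[i]] <- r
    }
  }
  ord <- order(is.na(ret), -ifelse(is.na(ret), Inf, ret),
               seq_len(k))
  out <- data.frame(row = ss[ord, 1], col = ss[ord, 2], slice = ss[ord, 3],
                    return = ret[ord], failed = is.na(ret[ord]),
                    reason = reason[ord])
  attr(out, "paths") <- paths[ord]
  out
}
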
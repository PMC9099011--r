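#' Value-iteration oracle for a finite voxel environment
#'
#' Computes Bellman-optimal state values under the same reward-on-entry
#' semantics as the Q-learning agent (terminal and action-less states have
#' value 0), iterating synchronous sweeps until the maximum change falls
#' below \code{tol}, and extracts the greedy optimal path from each start
#' state with the same lowest-action-index tie-break as the trained agent.
#' Used as the independent correctness reference for trained policies.
#'
#' @param env a \linkS4class{QEnvironment}.
#' @param gamma discount factor in [0, 1).
#' @param tol convergence tolerance on the sup-norm change.
#' @param maxIter sweep cap.
#' @return list with \code{values} (numeric array over the volume, NA off
#'   the node set), \code{returns} (optimal discounted return per start)
#'   and \code{paths} (list of greedy voxel paths, NULL where extraction
#'   failed).
#' @export
valueIterationOracle <- function(env, gamma = qConfig()@gamma, tol = 1e-10,
                                 maxIter = 100000L) {
  ix <- .nodeIndexing(env)
  V <- cpp_value_iteration(as.integer(ix$nodeIndex), env@dims,
                           as.numeric(env@reward), as.integer(env@terminal),
                           ix$nodeVoxels, gamma, tol, as.integer(maxIter))
  values <- array(NA_real_, dim = env@dims)
  values[ix$nodeVoxels] <- V
  off <- actionOffsets()
  d <- env@dims

  greedy <- function(start) {
    cur <- as.integer(start)
    if (env@terminal[cur[1], cur[2], cur[3]])
      return(list(path = matrix(cur, 1, 3),
                  ret = env@reward[cur[1], cur[2], cur[3]]))
    path <- list(cur)
    ret <- 0; gpow <- 1
    seen <- new.env(hash = TRUE)
    assign(paste(cur, collapse = ","), TRUE, envir = seen)
    for (step in seq_len(sum(env@admissible) + 1L)) {
      nb <- sweep(off, 2, cur, "+")
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L &
            nb[, 2] <= d[2] & nb[, 3] >= 1L & nb[, 3] <= d[3]
      ok[ok] <- env@admissible[nb[ok, , drop = FALSE]]
      acts <- which(ok)
      if (!length(acts)) return(NULL)
      qa <- vapply(acts, function(a) {
        dst <- nb[a, ]
        r <- env@reward[dst[1], dst[2], dst[3]]
        if (env@terminal[dst[1], dst[2], dst[3]]) r
        else r + gamma * values[dst[1], dst[2], dst[3]]
      }, 0)
      a <- acts[which.max(qa)]
      dest <- nb[a, ]
      ret <- ret + gpow * env@reward[dest[1], dest[2], dest[3]]
      gpow <- gpow * gamma
      path[[length(path) + 1L]] <- dest
      if (env@terminal[dest[1], dest[2], dest[3]])
        return(list(path = do.call(rbind, path), ret = ret))
      k <- paste(dest, collapse = ",")
      if (!is.null(seen[[k]])) return(NULL)
      assign(k, TRUE, envir = seen)
      cur <- dest
    }
    NULL
  }

  ss <- env@startStates
  paths <- vector("list", nrow(ss))
  rets <- rep(NA_real_, nrow(ss))
  for (i in seq_len(nrow(ss))) {
    g <- greedy(ss[i, ])
    if (!is.null(g)) { paths[[i]] <- g$path; rets[i] <- g$ret }
  }
  list(values = values, returns = rets, paths = paths)
}
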
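test_that("the value update reproduces hand-computed results", {
  expect_equal(qUpdate(0, 10, 0, 0.5, 0.9), 5, tolerance = 1e-15)
  # alpha = 1, gamma = 0: returns the reward exactly, any prior value
  for (q0 in c(-3, 0, 7.5)) expect_identical(qUpdate(q0, 4, 99, 1, 0), 4)
  expect_equal(qUpdate(2, -1, 4, 0.1, 0.9), 2.06, tolerance = 1e-15)
})

test_that("the update fixes its own Bellman-consistent points", {
  set.seed(31)
  for (k in 1:25) {
    reward <- runif(1, -10, 10); maxF <- runif(1, -10, 10)
    gamma <- runif(1, 0, 0.99); alpha <- runif(1, 0.01, 1)
    q <- reward + gamma * maxF
    expect_equal(qUpdate(q, reward, maxF, alpha, gamma), q,
                 tolerance = 1e-12)
  }
})

test_that("training is seed-deterministic and episodes = 0 leaves zeros", {
  env <- generateCorridorWorld(5, 2)$env
  a <- train(env, qConfig(episodes = 500L, seed = 10L))
  b <- train(env, qConfig(episodes = 500L, seed = 10L))
  expect_identical(a$qtable@q, b$qtable@q)
  expect_identical(a$stats, b$stats)
  c0 <- train(env, qConfig(episodes = 0L, seed = 10L))
  expect_true(all(c0$qtable@q == 0))
})

test_that("trained values stay inside the discount bound", {
  cw <- generateCorridorWorld(6, 3, hazardPenalty = 80)
  qc <- qConfig(episodes = 3000L, seed = 2L, gamma = 0.9)
  tr <- train(cw$env, qc)
  R <- max(abs(cw$env@reward))
  expect_true(all(abs(tr$qtable@q) <= R / (1 - qc@gamma) + 1e-9))
})

test_that("pure exploitation follows the argmax chain in the table", {
  env <- generateCorridorWorld(3, 1, gamma = 0.9)$env
  qt <- qTable(env)
  # steer the chain (2,2,1) -> (2,2,2) -> (2,2,3) -> goal (2,2,4)
  off <- actionOffsets()
  fwd <- which(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 1)
  for (s in 1:3) qt@q[qt@nodeIndex[2, 2, s], fwd] <- 10
  set.seed(1)
  ep <- runEpisode(env, qt, qConfig(epsilon = 0), start = c(2L, 2L, 1L))
  expect_identical(ep$trace, cbind(2L, 2L, 1:4))
  expect_identical(ep$cause, "terminal")

  # one step from the goal: the full goal reward
  set.seed(1)
  ep2 <- runEpisode(env, qt, qConfig(epsilon = 0), start = c(2L, 2L, 3L))
  expect_identical(ep2$return, 100)

  # step cap in an open field
  fe <- openFieldEnv()
  set.seed(1)
  ep3 <- runEpisode(fe, qTable(fe), qConfig(epsilon = 1, maxSteps = 5L),
                    start = c(3L, 3L, 3L))
  expect_lte(nrow(ep3$trace) - 1L, 5L)
  expect_identical(ep3$cause, "max_steps")
})

test_that("greedy extraction matches the oracle on a converged corridor world", {
  cw <- generateCorridorWorld(6, 2, gamma = 0.9)
  qc <- qConfig(episodes = 30000L, seed = 3L, gamma = 0.9)
  tr <- train(cw$env, qc)
  vi <- valueIterationOracle(cw$env, gamma = 0.9)
  ss <- cw$env@startStates
  for (i in seq_len(nrow(ss))) {
    got <- extractBestPath(tr$qtable, cw$env, ss[i, ], gamma = 0.9)
    expect_equal(got@totalReturn, vi$returns[i], tolerance = 1e-6)
  }
})

test_that("degenerate extractions are diagnosed, not looped", {
  cw <- generateCorridorWorld(4, 1)
  # start on the goal: single-node path carrying the goal reward
  r <- extractBestPath(qTable(cw$env), cw$env, cw$metadata$goal)
  expect_identical(nrow(r@path), 1L)
  expect_identical(r@totalReturn, 100)
  # all-zero table in an open field must hit the cycle guard
  fe <- openFieldEnv()
  expect_error(extractBestPath(qTable(fe), fe, c(3L, 3L, 3L)), "cycle")
  expect_error(extractBestPath(qTable(fe), fe, c(9L, 1L, 1L)), "not an environment node")
})

test_that("start ranking orders by greedy return with failures last", {
  # adjacent-to-goal start must rank first
  labels <- array(0L, c(7, 7, 7)); labels[4, 4, 6] <- 1L
  lm <- LabelMap(labels)
  env0 <- new("QEnvironment", dims = c(7L, 7L, 7L),
              admissible = array(TRUE, c(7, 7, 7)),
              reward = array(0, c(7, 7, 7)),
              terminal = array(FALSE, c(7, 7, 7)),
              startStates = matrix(c(4L, 4L, 5L, 4L, 4L, 1L), 2, 3,
                                   byrow = TRUE))
  env <- assignRewards(env0, lm, tinyCatalog(), qConfig(gamma = 0.9))
  tr <- train(env, qConfig(episodes = 8000L, seed = 6L, gamma = 0.9))
  rk <- rankStarts(tr$qtable, env, gamma = 0.9)
  expect_identical(unlist(rk[1, c("row", "col", "slice")], use.names = FALSE),
                   c(4L, 4L, 5L))
  expect_false(is.unsorted(-rk$return[!rk$failed]))

  # ranking matches the oracle ordering
  vi <- valueIterationOracle(env, gamma = 0.9)
  ord <- order(-vi$returns)
  got <- paste(rk$row, rk$col, rk$slice)
  want <- paste(env@startStates[ord, 1], env@startStates[ord, 2],
                env@startStates[ord, 3])
  expect_identical(got, want)

  # all starts failing: flagged, input order preserved
  fe <- openFieldEnv()
  rkf <- rankStarts(qTable(fe), fe)
  expect_true(all(rkf$failed))
  expect_identical(unlist(rkf[1, c("row", "col", "slice")],
                          use.names = FALSE), c(1L, 1L, 1L))
})

test_that("raising a structure's penalty never increases contact with it", {
  # non-terminal hazard slab with a gap between start and goal: the cheap
  # route crosses the slab directly, the safe route detours through the
  # gap; the greedy path must not touch the slab more often when the slab
  # costs more
  # the gap sits far enough laterally that (in Chebyshev moves) the detour
  # costs three extra steps, so it only pays off when the slab is expensive
  dims <- c(11L, 11L, 9L)
  labels <- array(0L, dims)
  labels[, , 5] <- 2L            # hazard slab ...
  labels[1, 1, 5] <- 0L          # ... with a gap in one corner
  labels[6, 6, 8] <- 1L          # tumor behind it
  lm <- LabelMap(labels)
  base <- new("QEnvironment", dims = dims,
              admissible = array(TRUE, dims), reward = array(0, dims),
              terminal = array(FALSE, dims),
              startStates = matrix(c(6L, 6L, 1L), 1))
  contacts <- sapply(c(2, 100), function(penalty) {
    cat2 <- tinyCatalog(vesselPenalty = penalty)
    counts <- sapply(1:5, function(seed) {
      env <- assignRewards(base, lm, cat2,
                           qConfig(terminalOnHit = FALSE, gamma = 0.9))
      tr <- train(env, qConfig(episodes = 30000L, seed = seed, gamma = 0.9,
                               epsilon = 1, epsilonEnd = 0.05))
      p <- extractBestPath(tr$qtable, env, c(4L, 4L, 1L), gamma = 0.9)
      sum(labels[p@path] == 2L)
    })
    mean(counts)
  })
  expect_identical(contacts[2], 0)     # detours through the gap
  expect_lte(contacts[2], contacts[1])
  expect_gte(contacts[1], 1)           # cheap slab is crossed directly
})
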
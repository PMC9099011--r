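test_that("entry-window enumeration matches hand-derived counts", {
  expect_identical(nrow(enumerateEntryWindows(c(8, 8, 4), 2)), 120L)
  # n = 4 on (8, 8, 4): side faces contribute zero
  expect_identical(nrow(enumerateEntryWindows(c(8, 8, 4), 4)), 32L)
  w <- enumerateEntryWindows(c(8, 8, 4), 4)
  expect_true(all(w$face %in% c("z_min", "z_max")))
  expect_error(enumerateEntryWindows(c(8, 8, 4), 8), "no windows")
})

test_that("enumeration equals brute-force placement over random geometries", {
  set.seed(21)
  for (k in 1:20) {
    dims <- sample(6:32, 3, replace = TRUE)
    n <- sample(1:8, 1)
    want <- bruteWindowCount(dims, n)
    if (want == 0L) {
      expect_error(enumerateEntryWindows(dims, n), "no windows")
    } else {
      w <- enumerateEntryWindows(dims, n)
      expect_identical(nrow(w), want)
      expect_false(anyDuplicated(w[, c("face", "u", "v")]) > 0)
    }
  }
})

test_that("goal-point selection is nearest with lexicographic tie-break", {
  vox <- matrix(c(5L, 5L, 8L,
                  5L, 5L, 9L,
                  7L, 5L, 8L), ncol = 3, byrow = TRUE)
  vox <- vox[order(vox[, 1], vox[, 2], vox[, 3]), ]
  gr <- new("GoalRegion", voxels = vox, goalPoint = vox[1, ], label = 1L)
  expect_identical(selectGoalPoint(gr, c(5, 5, 1)), c(5L, 5L, 8L))
  # (5,5,8) and (7,5,8) are equidistant from (6,5,1): lexicographic winner
  expect_identical(selectGoalPoint(gr, c(6, 5, 1)), c(5L, 5L, 8L))
  single <- new("GoalRegion", voxels = matrix(c(3L, 3L, 3L), 1),
                goalPoint = c(3L, 3L, 3L), label = 1L)
  expect_identical(selectGoalPoint(single, c(1, 9, 2)), c(3L, 3L, 3L))
})

test_that("center-line voxelization handles axis, diagonal and degenerate cases", {
  col8 <- traceCenterLine(c(4, 4, 1), c(4, 4, 8))
  expect_identical(col8, cbind(4L, 4L, 1:8))
  expect_identical(traceCenterLine(c(2, 2, 2), c(2, 2, 2)),
                   matrix(c(2L, 2L, 2L), 1))
  diag3 <- traceCenterLine(c(1, 1, 1), c(3, 3, 3))
  expect_setequal(voxKey(diag3), voxKey(denseLineOracle(c(1, 1, 1), c(3, 3, 3))))
  expect_error(traceCenterLine(c(0, 1, 1), c(2, 2, 2), dims = c(4, 4, 4)),
               "out of bounds")
})

test_that("voxelized segments equal the exact slab-intersection oracle", {
  set.seed(23)
  for (k in 1:60) {
    a <- sapply(c(32, 32, 32), function(d) sample(d, 1))
    b <- sapply(c(32, 32, 32), function(d) sample(d, 1))
    line <- traceCenterLine(a, b)
    expect_setequal(voxKey(line), voxKey(slabLineOracle(a, b)))
    # ordered, endpoints included, 26-adjacent steps
    expect_identical(line[1, ], as.integer(a))
    expect_identical(line[nrow(line), ], as.integer(b))
    if (nrow(line) > 1)
      expect_true(all(abs(diff(line)) <= 1L))
  }
})

test_that("corridor sweeps have the expected cross-sections and clip to bounds", {
  line <- cbind(8L, 8L, 1:10)
  expect_identical(sweepCorridor(line, 1, "z_min", "prism", c(16, 16, 16)),
                   line)
  c2 <- sweepCorridor(line, 2, "z_min", "prism", c(16, 16, 16))
  expect_identical(nrow(c2), 4L * 10L)
  # corner window: clipped, never out of bounds
  corner <- sweepCorridor(cbind(1L, 1L, 1:4), 4, "z_min", "prism", c(16, 16, 16))
  expect_true(all(corner >= 1L) && all(corner[, 1:2] <= 16L))
  expect_lt(nrow(corner), 16L * 4L)
  cyl <- sweepCorridor(line, 4, "z_min", "cylinder", c(16, 16, 16))
  expect_lt(nrow(cyl), nrow(sweepCorridor(line, 4, "z_min", "prism",
                                          c(16, 16, 16))))
})

test_that("corridor scoring counts per-voxel structure penalties", {
  lm <- tinyWorld()
  cat2 <- tinyCatalog()
  # corridor away from everything
  free <- cbind(1L, 1L, 1:3)
  expect_identical(scorePath(free, lm, cat2), 0)
  # exactly 3 vessel voxels at 50 each
  hit <- rbind(cbind(2:4, 4L, 8L), cbind(1L, 1L, 1L))
  expect_identical(scorePath(hit, lm, cat2), 150)
  # tumor voxels are reward, not penalty
  gr <- goalRegion(lm, cat2)
  expect_identical(scorePath(gr@voxels, lm, cat2), 0)
  # extracranial voxels score zero
  mask <- array(TRUE, dim = dim(lm)); mask[, 4L, 8L] <- FALSE
  expect_identical(scorePath(hit, lm, cat2, mask), 0)
  # uncatalogued label errors
  bad <- labels3d(lm); bad[1, 1, 1] <- 9L
  expect_error(scorePath(cbind(1L, 1L, 1L), LabelMap(bad), cat2),
               "uncatalogued")
})

test_that("scoring matches the brute-force intersection oracle and is monotone", {
  set.seed(29)
  penaltyById <- list("2" = 50)
  for (k in 1:15) {
    labels <- array(0L, c(12, 12, 12))
    labels[cbind(sample(12, 40, TRUE), sample(12, 40, TRUE),
                 sample(12, 40, TRUE))] <- 2L
    labels[6, 6, 6] <- 1L
    lm <- LabelMap(labels)
    mask <- array(stats::runif(12^3) > 0.2, c(12, 12, 12))
    corr <- unique(cbind(sample(12, 60, TRUE), sample(12, 60, TRUE),
                         sample(12, 60, TRUE)))
    want <- scoreOracle(corr, labels, penaltyById, 1L, mask)
    expect_equal(scorePath(corr, lm, tinyCatalog(), mask), want)
    # adding a labeled in-mask voxel never decreases the penalty
    vs <- which(labels == 2L & mask, arr.ind = TRUE)
    if (nrow(vs) > 0) {
      more <- unique(rbind(corr, vs[1, , drop = FALSE]))
      expect_gte(scorePath(more, lm, tinyCatalog(), mask),
                 scorePath(corr, lm, tinyCatalog(), mask))
    }
  }
})

test_that("the all-full-scoring funnel equals the exhaustive global top-k", {
  lm <- tinyWorld(c(16L, 16L, 16L))
  cat2 <- tinyCatalog()
  gr <- goalRegion(lm, cat2)
  windows <- enumerateEntryWindows(dim(lm), 2)
  cfg <- plannerConfig(cellDims = 2, stageSizes = c(200, 80, 40, 20),
                       stageSampling = c(0, 0, 0, 0))
  got <- stagedReduction(windows, gr, lm, cat2, config = cfg)

  # oracle: fully score every window's swept corridor, sort, take 20
  centers <- windowCenters(windows, dim(lm))
  score <- numeric(nrow(windows)); len <- integer(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    gp <- selectGoalPoint(gr, centers[i, ])
    line <- traceCenterLine(centers[i, ], gp)
    corr <- sweepCorridor(line, 2, windows$face[i], "prism", dim(lm))
    score[i] <- scorePath(corr, lm, cat2)
    len[i] <- nrow(line)
  }
  faceIdx <- match(windows$face, c("x_min", "x_max", "y_min", "y_max",
                                   "z_min", "z_max"))
  ord <- order(score, len, faceIdx, windows$u, windows$v)[1:20]
  expect_equal(sapply(got, pathPenalty), score[ord])
  expect_identical(vapply(got, function(p) paste(p@face, p@u, p@v), ""),
                   paste(windows$face[ord], windows$u[ord], windows$v[ord]))
  expect_false(is.unsorted(sapply(got, pathPenalty)))
})

test_that("staged reduction breaks ties by length and is deterministic", {
  lm <- tinyWorld()
  cat2 <- tinyCatalog()
  gr <- goalRegion(lm, cat2)
  windows <- enumerateEntryWindows(dim(lm), 2)
  cfg <- plannerConfig(cellDims = 2, stageSizes = c(100, 80, 40, 20))
  a <- stagedReduction(windows, gr, lm, cat2, config = cfg)
  b <- stagedReduction(windows, gr, lm, cat2, config = cfg)
  expect_identical(lapply(a, function(p) p@centerLine),
                   lapply(b, function(p) p@centerLine))
  expect_identical(sapply(a, pathPenalty), sapply(b, pathPenalty))
  pen <- sapply(a, pathPenalty)
  len <- sapply(a, function(p) p@lengthVoxels)
  eq <- which(diff(pen) == 0)
  if (length(eq)) expect_true(all(len[eq] <= len[eq + 1L]))

  # fewer windows than the final stage size: all returned, sorted
  few <- windows[1:7, ]
  out <- stagedReduction(few, gr, lm, cat2, config = cfg)
  expect_length(out, 7L)
  expect_false(is.unsorted(sapply(out, pathPenalty)))
})
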
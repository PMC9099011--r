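# Independent oracles and small fixture builders shared by the suite.
# Each oracle is a deliberately naive implementation, kept separate from
# the code paths it checks.

# Dense-sampling segment voxelization: sample the segment between the two
# voxel centers at steps of 1e-3 of its length and map each sample to its
# containing voxel (floor; boundary points to the upper voxel).
denseLineOracle <- function(start, goal) {
  p <- start - 0.5
  q <- goal - 0.5
  if (all(start == goal)) return(matrix(as.integer(start), 1, 3))
  t <- seq(0, 1, length.out = 1001L)
  pts <- cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]),
               p[3] + t * (q[3] - p[3]))
  vox <- floor(pts) + 1L
  unique(vox)
}

voxKey <- function(m) paste(m[, 1], m[, 2], m[, 3])

# Brute-force unit-stride window placement count under the convention that
# the window plus one guard voxel must fit along each in-face axis.
bruteWindowCount <- function(dims, n) {
  facePairs <- list(c(dims[2], dims[3]), c(dims[2], dims[3]),
                    c(dims[1], dims[3]), c(dims[1], dims[3]),
                    c(dims[1], dims[2]), c(dims[1], dims[2]))
  total <- 0L
  for (fp in facePairs) {
    for (u in seq_len(fp[1]))
      for (v in seq_len(fp[2]))
        if (u + n <= fp[1] && v + n <= fp[2]) total <- total + 1L
  }
  total
}

# Scalar even-odd point-in-polygon by explicit ray casting, one point at a
# time (independent of the vectorized rasterizer).
pointInPolyOracle <- function(pr, pc, poly) {
  nv <- nrow(poly)
  inside <- FALSE
  j <- nv
  for (i in seq_len(nv)) {
    ri <- poly[i, 1]; ci <- poly[i, 2]
    rj <- poly[j, 1]; cj <- poly[j, 2]
    if ((ri > pr) != (rj > pr)) {
      xcross <- (cj - ci) * (pr - ri) / (rj - ri) + ci
      if (pc < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force corridor scoring from a per-id penalty map.
scoreOracle <- function(corridor, labelArr, penaltyById, goalId, maskArr) {
  tot <- 0
  for (i in seq_len(nrow(corridor))) {
    v <- corridor[i, ]
    if (!maskArr[v[1], v[2], v[3]]) next
    lab <- labelArr[v[1], v[2], v[3]]
    if (lab == 0L || lab == goalId) next
    tot <- tot + penaltyById[[as.character(lab)]]
  }
  tot
}

# Two-structure catalog used widely: tumor (goal) + one vessel.
tinyCatalog <- function(vesselPenalty = 50) {
  StructureCatalog(data.frame(
    id = c(1L, 2L), name = c("tumor", "vessel"),
    category = c("tumor", "artery"), penalty = c(0, vesselPenalty),
    is_goal = c(TRUE, FALSE)))
}

# A small labeled box: spherical tumor in the middle of the far end, one
# vessel plane, all inside an all-TRUE mask.
tinyWorld <- function(dims = c(16L, 16L, 16L), vesselSlice = 8L,
                      tumorRadius = 2.5) {
  labels <- array(0L, dim = dims)
  ctr <- c(dims[1] / 2, dims[2] / 2, dims[3] - 3)
  for (s in seq_len(dims[3])) for (cc in seq_len(dims[2]))
    for (r in seq_len(dims[1])) {
      if ((r - ctr[1])^2 + (cc - ctr[2])^2 + (s - ctr[3])^2 <= tumorRadius^2)
        labels[r, cc, s] <- 1L
    }
  labels[, 4L, vesselSlice] <- ifelse(labels[, 4L, vesselSlice] == 0L, 2L,
                                      labels[, 4L, vesselSlice])
  LabelMap(labels)
}

# Open-field environment (no terminals) for cycle-guard tests.
openFieldEnv <- function(dims = c(5L, 5L, 5L)) {
  new("QEnvironment", dims = as.integer(dims),
      admissible = array(TRUE, dim = dims),
      reward = array(-1, dim = dims),
      terminal = array(FALSE, dim = dims),
      startStates = matrix(c(1L, 1L, 1L, 3L, 3L, 3L), 2, 3, byrow = TRUE))
}
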
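# Exact brute-force segment-voxelization oracle: for every voxel in the
# segment's bounding box, intersect the segment's parameter interval with
# the voxel's axis slabs and keep voxels with a positive-length chord.
# Corner/edge touches (zero chord) are excluded. Independent of the
# boundary-crossing traversal it checks.
slabLineOracle <- function(start, goal) {
  p <- start - 0.5
  d <- goal - start
  lo <- pmin(start, goal); hi <- pmax(start, goal)
  g <- expand.grid(r = lo[1]:hi[1], c = lo[2]:hi[2], s = lo[3]:hi[3])
  t0 <- rep(0, nrow(g)); t1 <- rep(1, nrow(g)); ok <- rep(TRUE, nrow(g))
  for (ax in 1:3) {
    b0 <- g[[ax]] - 1; b1 <- g[[ax]]
    if (d[ax] == 0) {
      ok <- ok & (p[ax] > b0 & p[ax] < b1)
    } else {
      ta <- (b0 - p[ax]) / d[ax]; tb <- (b1 - p[ax]) / d[ax]
      t0 <- pmax(t0, pmin(ta, tb))
      t1 <- pmin(t1, pmax(ta, tb))
    }
  }
  ok <- ok & (t1 - t0 > 1e-12)
  m <- as.matrix(g[ok, , drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}
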
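# Head-mask derivation: extracranial voxels are excluded from scoring and
# from the Stage-2 environment, so candidate corridors are only charged for
# structures inside the head.

.otsu <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / (rng[2] - rng[1]) * nbins)),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  muT <- mu[nbins]
  sigma <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma[!is.finite(sigma)] <- 0
  k <- which.max(sigma)
  rng[1] + k / nbins * (rng[2] - rng[1])
}

.shift3 <- function(a, dr, dc, ds) {
  d <- dim(a)
  out <- array(FALSE, d)
  rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
  cs <- max(1, 1 + dc):min(d[2], d[2] + dc)
  ss <- max(1, 1 + ds):min(d[3], d[3] + ds)
  out[rs, cs, ss] <- a[rs - dr, cs - dc, ss - ds]
  out
}

.dilate3 <- function(a) {
  out <- a
  for (dr in -1:1) for (dc in -1:1) for (ds in -1:1) {
    if (dr == 0 && dc == 0 && ds == 0) next
    out <- out | .shift3(a, dr, dc, ds)
  }
  out
}

.erode3 <- function(a) !.dilate3(!a)

#' Derive the head mask of a volume
#'
#' Thresholds the intensities (Otsu by default), keeps the largest
#' 26-connected component, and closes it morphologically with a 3x3x3
#' element. Supply \code{threshold} to override Otsu.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param threshold optional explicit intensity threshold.
#' @param closeIter closing iterations (default 1).
#' @return logical array of in-head voxels.
#' @export
headMask <- function(volume, threshold = NULL, closeIter = 1L) {
  x <- intensities(volume)
  if (is.null(threshold)) threshold <- .otsu(as.vector(x))
  m <- x > threshold
  if (!any(m)) stop("head mask is empty at this threshold")
  comp <- cpp_connected_components(as.logical(m), dim(x))
  tab <- tabulate(comp)
  keep <- which.max(tab)
  m <- array(comp == keep, dim = dim(x))
  for (i in seq_len(closeIter)) m <- .erode3(.dilate3(m))
  m
}
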
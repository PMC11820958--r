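# Independent oracles and fixture builders used across the test suite.
# These deliberately use naive algorithms (exhaustive loops, BFS flood fill)
# that share no code with the package implementation.

# brute-force binary median filter on one 3D volume: per-voxel window sum
# against the full (zero-padded) window volume
bruteMedian3 <- function(v, window) {
  h <- (window - 1) %/% 2
  d <- dim(v)
  out <- array(0L, d)
  need <- prod(window) / 2
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    xs <- max(1, x - h[1]):min(d[1], x + h[1])
    ys <- max(1, y - h[2]):min(d[2], y + h[2])
    zs <- max(1, z - h[3]):min(d[3], z + h[3])
    out[x, y, z] <- as.integer(sum(v[xs, ys, zs]) > need)
  }
  out
}

# BFS flood-fill connected components of a 4D binary array under per-axis
# half-extents hw; returns a per-ROI-voxel label vector (voxels in linear
# index order), labeled in order of first discovery
bfsComponents4 <- function(arr, hw = c(1, 1, 1, 1)) {
  d <- dim(arr)
  idx <- which(arr != 0)
  if (!length(idx)) return(integer(0))
  coords <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dx = -hw[1]:hw[1], dy = -hw[2]:hw[2],
                                dz = -hw[3]:hw[3], dt = -hw[4]:hw[4]))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lin <- function(cc)
    (cc[, 1] - 1) + d[1] * (cc[, 2] - 1) + d[1] * d[2] * (cc[, 3] - 1) +
      d[1] * d[2] * d[3] * (cc[, 4] - 1) + 1
  labels <- integer(length(idx))
  cur <- 0L
  for (s in seq_along(idx)) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    labels[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- offs + matrix(coords[v, ], nrow(offs), 4, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3] & nb[, 4] >= 1 & nb[, 4] <= d[4]
      j <- match(lin(nb[ok, , drop = FALSE]), idx)
      j <- j[!is.na(j)]
      fresh <- j[labels[j] == 0L]
      labels[fresh] <- cur
      queue <- c(queue, fresh)
    }
  }
  labels
}

# canonical form of a labeling (relabel by first appearance) so that two
# partitions can be compared regardless of numbering
canonLabels <- function(lab) match(lab, unique(lab))

# a solid binary sphere of given radius centered in a volume
sphereVolume <- function(d, center, radius) {
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  v <- array(0L, d)
  inside <- (g$x - center[1])^2 + (g$y - center[2])^2 +
    (g$z - center[3])^2 <= radius^2
  v[as.matrix(g[inside, ])] <- 1L
  v
}

# a component set built directly from a coordinate matrix (one label each)
syntheticComponent <- function(coords, dims, label = 1L, voxelSize = c(1, 1, 1)) {
  CellComponentSet(coords, rep(label, nrow(coords)), dims, voxelSize)
}

# bright-disks-on-dim-background test slice with known disk masks
diskSlice <- function(n = 64, centers = list(c(20, 20), c(45, 45)),
                      radius = 10, seed = 9) {
  set.seed(seed)
  sl <- matrix(rbeta(n * n, 2, 8) * 255, n, n)
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  disk <- rep(FALSE, n * n)
  for (cc in centers)
    disk <- disk | (sqrt((xy$x - cc[1])^2 + (xy$y - cc[2])^2) <= radius)
  sl[as.matrix(xy[disk, ])] <- (0.5 + 0.5 * rbeta(sum(disk), 8, 2)) * 255
  list(slice = sl, diskMask = disk, xy = xy, centers = centers,
       radius = radius)
}
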
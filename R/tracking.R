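# Segmentation and tracking by 4D connected-component labeling.
#
# Every ROI voxel (x, y, z, t) is a node; two voxels are connected when each
# coordinate offset has magnitude at most the kernel half-extent (default
# kernel [3,3,3,3]: all 80 surrounding offsets in 4D). A 4D component is one
# tracked cell across time. A temporal split-merge step rejoins components
# separated by low signal-to-noise timepoints, and a minimum-size filter
# removes small isolated clusters.

# find adjacencies between voxel rows under a set of coordinate offsets;
# returns a 2-column matrix of row indices (i, j)
.voxelEdges <- function(coords, dims, offsets) {
  lin <- .linearIndex(coords, dims)
  edges <- vector("list", nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    ok <- rep(TRUE, nrow(coords))
    for (a in 1:4) {
      ca <- coords[, a] + off[a]
      ok <- ok & ca >= 1L & ca <= dims[a]
    }
    if (!any(ok)) next
    nb <- coords[ok, , drop = FALSE]
    nb <- nb + matrix(off, nrow(nb), 4, byrow = TRUE)
    j <- match(.linearIndex(nb, dims), lin)
    hit <- !is.na(j)
    if (any(hit))
      edges[[o]] <- cbind(which(ok)[hit], j[hit])
  }
  do.call(rbind, c(edges, list(matrix(0L, 0, 2))))
}

# union-find with path halving; returns root per element after processing
# all edges
.unionFind <- function(n, edges) {
  parent <- seq_len(n)
  if (nrow(edges)) {
    ei <- edges[, 1]; ej <- edges[, 2]
    for (e in seq_along(ei)) {
      a <- ei[e]
      while (parent[a] != a) {
        parent[a] <- parent[parent[a]]
        a <- parent[a]
      }
      b <- ej[e]
      while (parent[b] != b) {
        parent[b] <- parent[parent[b]]
        b <- parent[b]
      }
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  # final root resolution
  for (i in seq_len(n)) {
    a <- i
    while (parent[a] != a) {
      parent[a] <- parent[parent[a]]
      a <- parent[a]
    }
    parent[i] <- a
  }
  parent
}

# offsets with |off_a| <= hw_a per axis; only the "positive" half so that
# each unordered voxel pair is visited once
.halfOffsets <- function(hw) {
  g <- as.matrix(expand.grid(dx = -hw[1]:hw[1], dy = -hw[2]:hw[2],
                             dz = -hw[3]:hw[3], dt = -hw[4]:hw[4]))
  key <- g[, 1] + 1e3 * g[, 2] + 1e6 * g[, 3] + 1e9 * g[, 4]
  g[key > 0, , drop = FALSE]
}

# relabel so components are numbered by the lexicographic (t, z, y, x) order
# of their minimal voxel, i.e. by minimal linear index
.compactLabels <- function(roots, lin) {
  if (!length(roots)) return(integer(0))
  minLin <- tapply(lin, roots, min)
  ord <- order(minLin)
  map <- integer(max(roots))
  map[as.integer(names(minLin))[ord]] <- seq_along(ord)
  map[roots]
}

#' Label 4D connected components
#'
#' Partitions the ROI voxels of a binary stack into maximal connected
#' components under the declared neighborhood kernel. With the default
#' kernel \code{c(3, 3, 3, 3)} all \eqn{3^4 - 1 = 80} surrounding offsets
#' are neighbors, so a component extends through space and time jointly.
#' Labels are contiguous positive integers numbered deterministically by
#' each component's minimal voxel in \code{(t, z, y, x)} order.
#'
#' @param binary a \linkS4class{BinaryStack4D} or 4D 0/1 array.
#' @param kernel integer(4), odd kernel extents per axis (x, y, z, t);
#'   voxels are connected iff each coordinate offset magnitude is at most
#'   the kernel half-extent.
#' @param voxelSize numeric(3), micrometres per voxel, carried through to
#'   downstream reporting.
#' @return A \linkS4class{CellComponentSet}.
#' @export
labelComponents4D <- function(binary, kernel = c(3, 3, 3, 3),
                              voxelSize = c(1, 1, 1)) {
  kernel <- as.integer(kernel)
  if (length(kernel) != 4L || any(kernel < 1L) || any(kernel %% 2L == 0L))
    stop("kernel extents must be four odd integers >= 1", call. = FALSE)
  arr <- .asArray4(binary)
  d <- dim(arr)
  idx <- which(arr != 0)
  if (!length(idx))
    return(CellComponentSet(matrix(integer(0), 0, 4), integer(0), d,
                            voxelSize))
  coords <- arrayInd(idx, d)
  hw <- (kernel - 1L) %/% 2L
  edges <- .voxelEdges(coords, d, .halfOffsets(hw))
  roots <- .unionFind(nrow(coords), edges)
  label <- .compactLabels(roots, .linearIndex(coords, d))
  CellComponentSet(coords, label, d, voxelSize)
}

#' Merge components split by low signal-to-noise timepoints
#'
#' An interim timepoint with poor signal can split one cell's 4D component
#' into two (the cell is reported lost and then new). This step merges two
#' components when any voxel of one lies within the spatial merge window of
#' a voxel of the other at the same or a nearby timepoint (temporal distance
#' at most \code{gap + 1}); merging is transitive. With all spatial
#' half-widths 0 the component set is returned unchanged.
#'
#' @param comps a \linkS4class{CellComponentSet}.
#' @param halfwidth integer(3), spatial merge half-widths in voxels per axis
#'   (default \code{c(2, 2, 2)}).
#' @param gap tolerated temporal gap in timepoints (default 1): components
#'   merge across up to \code{gap} missing timepoints.
#' @return A \linkS4class{CellComponentSet} with merged, renumbered labels.
#' @export
mergeSplitComponents <- function(comps, halfwidth = c(2, 2, 2), gap = 1L) {
  stopifnot(methods::is(comps, "CellComponentSet"))
  halfwidth <- as.integer(halfwidth)
  gap <- as.integer(gap)
  stopifnot(length(halfwidth) == 3L, all(halfwidth >= 0L), gap >= 0L)
  if (all(halfwidth == 0L) || !nrow(comps@coords)) return(comps)
  offsets <- .halfOffsets(c(halfwidth, gap + 1L))
  edges <- .voxelEdges(comps@coords, comps@dims, offsets)
  if (nrow(edges)) {
    la <- comps@label[edges[, 1]]
    lb <- comps@label[edges[, 2]]
    cross <- la != lb
    pairs <- cbind(la[cross], lb[cross])
  } else {
    pairs <- matrix(0L, 0, 2)
  }
  nLab <- max(comps@label)
  roots <- .unionFind(nLab, unique(pairs))
  merged <- roots[comps@label]
  label <- .compactLabels(merged, .linearIndex(comps@coords, comps@dims))
  CellComponentSet(comps@coords, label, comps@dims, comps@voxelSize)
}

#' Remove components smaller than a minimum node count
#'
#' Components whose total 4D voxel count (across all timepoints) is below
#' \code{minSize} are removed; a component with exactly \code{minSize}
#' voxels is kept. Remaining labels are renumbered deterministically.
#'
#' @param comps a \linkS4class{CellComponentSet}.
#' @param minSize minimum voxel count (default 30).
#' @return A filtered \linkS4class{CellComponentSet}.
#' @export
filterSmallComponents <- function(comps, minSize = 30L) {
  stopifnot(methods::is(comps, "CellComponentSet"), minSize >= 1)
  if (!nrow(comps@coords)) return(comps)
  sizes <- cellSizes(comps)
  keep <- sizes[comps@label] >= minSize
  coords <- comps@coords[keep, , drop = FALSE]
  lab <- comps@label[keep]
  label <- .compactLabels(lab, .linearIndex(coords, comps@dims))
  CellComponentSet(coords, label, comps@dims, comps@voxelSize)
}

# presence spans -> per-timepoint fate table; shared by classifyFates,
# stratifyByDepth and the synthetic-scene ground truth. Presence is counted
# over the [first, last] interval so that cells bridged across low-signal
# gaps by the merge step count as present throughout.
.fatesFromSpans <- function(first, last, T) {
  ts <- seq_len(T)
  nTotal <- vapply(ts, function(t) sum(first <= t & last >= t), integer(1))
  nNew <- vapply(ts, function(t) if (t < T) sum(first == t + 1L) else 0L,
                 integer(1))
  nLost <- vapply(ts, function(t) if (t < T) sum(last == t) else 0L,
                  integer(1))
  data.frame(timepoint = ts, n_total = nTotal, n_new = nNew, n_lost = nLost)
}

#' Classify per-cell fates and tabulate them per timepoint
#'
#' For each component the first and last timepoints with presence define its
#' fate: a component first present at \eqn{t+1} counts as new at index
#' \eqn{t}; one last present at \eqn{t < T} counts as lost at index \eqn{t}.
#' Totals count components whose \eqn{[first, last]} span covers the
#' timepoint, so the conservation identity
#' \eqn{n_{total}(t+1) = n_{total}(t) + n_{new}(t) - n_{lost}(t)} holds.
#'
#' @param comps a filtered \linkS4class{CellComponentSet}.
#' @return A list with \code{fates} (data.frame: timepoint, n_total, n_new,
#'   n_lost) and \code{cells} (data.frame: one row per cell with first/last
#'   presence, total size, and the centroid at first presence in voxels and
#'   micrometres).
#' @export
classifyFates <- function(comps) {
  stopifnot(methods::is(comps, "CellComponentSet"))
  T <- comps@dims[4]
  if (!nrow(comps@coords)) {
    return(list(fates = .fatesFromSpans(integer(0), integer(0), T),
                cells = data.frame(cell_id = integer(0), first_t = integer(0),
                                   last_t = integer(0), size_total = integer(0),
                                   x_vox = numeric(0), y_vox = numeric(0),
                                   z_vox = numeric(0), x_um = numeric(0),
                                   y_um = numeric(0), z_um = numeric(0))))
  }
  lab <- comps@label
  ids <- seq_len(max(lab))
  first <- as.integer(tapply(comps@coords[, 4], lab, min)[as.character(ids)])
  last <- as.integer(tapply(comps@coords[, 4], lab, max)[as.character(ids)])
  sizes <- cellSizes(comps)
  cent <- t(vapply(ids, function(i) {
    sel <- lab == i & comps@coords[, 4] == first[i]
    colMeans(comps@coords[sel, 1:3, drop = FALSE])
  }, numeric(3)))
  vs <- comps@voxelSize
  cells <- data.frame(cell_id = ids, first_t = first, last_t = last,
                      size_total = sizes,
                      x_vox = cent[, 1], y_vox = cent[, 2], z_vox = cent[, 3],
                      x_um = (cent[, 1] - 1) * vs[1],
                      y_um = (cent[, 2] - 1) * vs[2],
                      z_um = (cent[, 3] - 1) * vs[3])
  list(fates = .fatesFromSpans(first, last, T), cells = cells)
}

#' Per-(cell, timepoint) record table
#'
#' One row per component and timepoint with presence: voxel count and
#' centroid in voxels and micrometres, plus first/last presence and new/lost
#' flags. Rows are ordered by cell id, then timepoint.
#'
#' @param comps a \linkS4class{CellComponentSet}.
#' @return A data.frame.
#' @export
cellTable <- function(comps) {
  stopifnot(methods::is(comps, "CellComponentSet"))
  T <- comps@dims[4]
  if (!nrow(comps@coords))
    return(data.frame(cell_id = integer(0), timepoint = integer(0),
                      n_voxels = integer(0), x_vox = numeric(0),
                      y_vox = numeric(0), z_vox = numeric(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      first_t = integer(0), last_t = integer(0),
                      is_new = integer(0), is_lost = integer(0)))
  key <- interaction(comps@label, comps@coords[, 4], drop = TRUE)
  grp <- split(seq_len(nrow(comps@coords)), key)
  rows <- lapply(grp, function(sel) {
    cc <- comps@coords[sel, , drop = FALSE]
    data.frame(cell_id = comps@label[sel[1]], timepoint = cc[1, 4],
               n_voxels = nrow(cc),
               x_vox = mean(cc[, 1]), y_vox = mean(cc[, 2]),
               z_vox = mean(cc[, 3]))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$cell_id, tab$timepoint), , drop = FALSE]
  vs <- comps@voxelSize
  tab$x_um <- (tab$x_vox - 1) * vs[1]
  tab$y_um <- (tab$y_vox - 1) * vs[2]
  tab$z_um <- (tab$z_vox - 1) * vs[3]
  spans <- classifyFates(comps)$cells
  tab$first_t <- spans$first_t[tab$cell_id]
  tab$last_t <- spans$last_t[tab$cell_id]
  tab$is_new <- as.integer(tab$first_t > 1L)
  tab$is_lost <- as.integer(tab$last_t < T)
  rownames(tab) <- NULL
  tab
}

#' Stratify fate tables by cortical depth
#'
#' Each cell is assigned to one depth bin from its z-centroid at first
#' presence, with depth measured from the first z-slice (assumed pial
#' surface): \code{depth_um = (z_centroid - 1) * voxelSize_z}. Cells deeper
#' than the last bin edge go to an overflow bin with a warning. Per-bin fate
#' tables use the same conventions as [classifyFates()], so they sum to the
#' unstratified table.
#'
#' @param comps a \linkS4class{CellComponentSet}.
#' @param binEdges ascending depth bin edges in micrometres, e.g.
#'   \code{c(0, 100, 200, 300)} for 100 um strata.
#' @return A list with \code{bins} (named list of per-bin fate tables,
#'   including \code{"overflow"} when occupied) and \code{assignment}
#'   (data.frame: cell_id, depth_um, bin).
#' @export
stratifyByDepth <- function(comps, binEdges = c(0, 100, 200, 300)) {
  stopifnot(methods::is(comps, "CellComponentSet"),
            length(binEdges) >= 2L, !is.unsorted(binEdges, strictly = TRUE))
  cf <- classifyFates(comps)
  cells <- cf$cells
  T <- comps@dims[4]
  depth <- cells$z_um
  if (nrow(cells) && any(depth < binEdges[1]))
    stop("cell depth below the first bin edge", call. = FALSE)
  bin <- findInterval(depth, binEdges, rightmost.closed = FALSE)
  over <- bin >= length(binEdges)
  if (any(over))
    warning(sum(over), " cell(s) deeper than the last bin edge assigned to ",
            "the overflow bin")
  nb <- length(binEdges) - 1L
  binNames <- sprintf("[%g,%g)", binEdges[-length(binEdges)], binEdges[-1])
  bins <- lapply(seq_len(nb), function(b) {
    sel <- bin == b & !over
    .fatesFromSpans(cells$first_t[sel], cells$last_t[sel], T)
  })
  names(bins) <- binNames
  if (any(over))
    bins[["overflow"]] <- .fatesFromSpans(cells$first_t[over],
                                          cells$last_t[over], T)
  assignment <- data.frame(cell_id = cells$cell_id, depth_um = depth,
                           bin = ifelse(over, "overflow", binNames[pmin(bin, nb)]))
  list(bins = bins, assignment = assignment)
}
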
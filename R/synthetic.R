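# Seeded synthetic 4D scenes with known ground truth.
#
# The generator emulates the regime of longitudinal two-photon imaging of
# fluorescent somas: beta-distributed background, bright quasi-spherical
# somas (ellipsoidal in voxel space to reflect z-anisotropic sampling) whose
# cores saturate the 8-bit range, dimmer thin filaments (myelin-sheath-like
# noise), multiplicative fluorescence attenuation with depth, scripted
# per-cell appearance/disappearance times, and optional low-signal
# timepoints that rescale the whole volume.

#' Build and validate a synthetic scene script
#'
#' A scene script fully determines a synthetic stack (given its seed):
#' volume shape, per-cell geometry and presence span, filament noise,
#' intensity distributions, depth attenuation and low-SNR timepoints.
#'
#' @param dims integer(4), volume shape (I, J, K, T).
#' @param cells data.frame with columns \code{x, y, z} (center voxel),
#'   \code{rxy, rz} (ellipsoid radii in voxels, \code{rxy >= 2}),
#'   \code{first_t, last_t} (presence span) and \code{peak} (peak intensity
#'   on the 0-255 scale before clipping; values above 255 produce saturated
#'   cores).
#' @param filaments optional data.frame with columns \code{x1, y1, z1, x2,
#'   y2, z2, thickness, intensity}: straight 3D segments of thickness 1-2
#'   voxels, dimmer than somas.
#' @param bgShape,somaShape beta shape parameters \code{c(alpha, beta)} of
#'   the background and soma intensity distributions on \eqn{[0, 1]}.
#' @param attenuation depth attenuation coefficient \eqn{\lambda}: signal at
#'   slice z is scaled by \eqn{\exp(-\lambda (z - 1))}.
#' @param lowSnr optional data.frame with columns \code{t, factor}: at the
#'   listed timepoints the whole volume is multiplied by \code{factor}.
#' @param voxelSize numeric(3), micrometres per voxel.
#' @param seed integer seed; scenes are bit-identical given the same script.
#' @param mergeWindow spatial merge half-width assumed when validating cell
#'   separation (centers must be farther apart than the sum of radii plus
#'   twice this margin, unless \code{allowOverlap}).
#' @param allowOverlap set TRUE to script colliding cells deliberately.
#' @return A validated list of class \code{"SceneScript"}.
#' @export
sceneScript <- function(dims, cells = NULL, filaments = NULL,
                        bgShape = c(2, 8), somaShape = c(8, 2),
                        attenuation = 0.01, lowSnr = NULL,
                        voxelSize = c(1, 1, 1), seed = 1L,
                        mergeWindow = 2L, allowOverlap = FALSE) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 4L, all(dims >= 1L))
  if (is.null(cells))
    cells <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        rxy = numeric(0), rz = numeric(0),
                        first_t = integer(0), last_t = integer(0),
                        peak = numeric(0))
  stopifnot(all(c("x", "y", "z", "rxy", "rz", "first_t", "last_t", "peak")
                %in% names(cells)))
  if (nrow(cells)) {
    stopifnot(all(cells$first_t >= 1L), all(cells$last_t <= dims[4]),
              all(cells$first_t <= cells$last_t), all(cells$rxy >= 2))
    if (!allowOverlap && nrow(cells) > 1L) {
      for (i in seq_len(nrow(cells) - 1L)) for (j in (i + 1L):nrow(cells)) {
        dx <- abs(cells$x[i] - cells$x[j])
        dy <- abs(cells$y[i] - cells$y[j])
        dz <- abs(cells$z[i] - cells$z[j])
        sepXY <- cells$rxy[i] + cells$rxy[j] + 2 * mergeWindow
        sepZ <- cells$rz[i] + cells$rz[j] + 2 * mergeWindow
        if (max(dx, dy) <= sepXY && dz <= sepZ &&
            sqrt(dx^2 + dy^2 + dz^2) <=
              max(cells$rxy[i] + cells$rxy[j], cells$rz[i] + cells$rz[j]) +
              2 * mergeWindow)
          stop("cells ", i, " and ", j, " are closer than the scripted ",
               "separation margin; set allowOverlap = TRUE to script a ",
               "collision", call. = FALSE)
      }
    }
  }
  if (!is.null(lowSnr))
    stopifnot(all(c("t", "factor") %in% names(lowSnr)),
              all(lowSnr$t >= 1L & lowSnr$t <= dims[4]))
  structure(list(dims = dims, cells = cells, filaments = filaments,
                 bgShape = bgShape, somaShape = somaShape,
                 attenuation = attenuation, lowSnr = lowSnr,
                 voxelSize = as.numeric(voxelSize), seed = as.integer(seed),
                 allowOverlap = isTRUE(allowOverlap)),
            class = "SceneScript")
}

# voxel coordinates, normalized ellipsoid distance d <= 1 and soft edge
# falloff for one cell
.cellMask <- function(cell, dims) {
  xr <- max(1, floor(cell$x - cell$rxy)):min(dims[1], ceiling(cell$x + cell$rxy))
  yr <- max(1, floor(cell$y - cell$rxy)):min(dims[2], ceiling(cell$y + cell$rxy))
  zr <- max(1, floor(cell$z - cell$rz)):min(dims[3], ceiling(cell$z + cell$rz))
  g <- expand.grid(x = xr, y = yr, z = zr)
  d <- sqrt(((g$x - cell$x) / cell$rxy)^2 + ((g$y - cell$y) / cell$rxy)^2 +
              ((g$z - cell$z) / cell$rz)^2)
  inside <- d <= 1
  # soft 1-voxel edge: full intensity >= 1 voxel inside the surface
  falloff <- pmin(1, pmax(0, (1 - d[inside]) * cell$rxy))
  list(coords = as.matrix(g[inside, , drop = FALSE]), falloff = falloff)
}

# voxels of a straight 3D segment of the given thickness (1 or 2)
.filamentVoxels <- function(f, dims) {
  len <- max(abs(c(f$x2 - f$x1, f$y2 - f$y1, f$z2 - f$z1)), 1)
  s <- seq(0, 1, length.out = ceiling(len) * 2 + 1)
  pts <- unique(cbind(round(f$x1 + s * (f$x2 - f$x1)),
                      round(f$y1 + s * (f$y2 - f$y1)),
                      round(f$z1 + s * (f$z2 - f$z1))))
  if (f$thickness >= 2) {
    near <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    pts <- unique(rbind(pts,
                        do.call(rbind, lapply(seq_len(nrow(near)), function(i)
                          sweep(pts, 2, near[i, ], `+`)))))
  }
  ok <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
        pts[, 2] >= 1 & pts[, 2] <= dims[2] &
        pts[, 3] >= 1 & pts[, 3] <= dims[3]
  pts[ok, , drop = FALSE]
}

#' Generate a synthetic 4D scene with ground truth
#'
#' Renders the script deterministically under its seed: background voxels
#' are drawn from the background beta distribution scaled to \eqn{[0, 255]};
#' soma voxels from the soma beta scaled by the cell's peak intensity, the
#' soft edge falloff and the depth attenuation, then clipped to 255 and
#' combined with the background by maximum; filaments likewise at their
#' (dimmer) scripted intensity. Low-SNR timepoints rescale the volume before
#' 8-bit rounding. The ground-truth fate table is derived from the scripted
#' presence spans with the same conventions as [classifyFates()].
#'
#' @param script a \code{"SceneScript"} from [sceneScript()].
#' @return A list with \code{stack} (an \linkS4class{ImageStack4D}),
#'   \code{truth} (list: \code{fates} data.frame, \code{cells} the script's
#'   cell table, \code{masks} per-cell 3D voxel coordinate matrices).
#' @export
generateScene <- function(script) {
  stopifnot(inherits(script, "SceneScript"))
  d <- script$dims
  atten <- exp(-script$attenuation * (seq_len(d[3]) - 1))
  masks <- lapply(seq_len(nrow(script$cells)), function(i)
    .cellMask(script$cells[i, ], d))
  # ground-truth masks must be disjoint unless a collision was scripted
  if (length(masks) > 1L && !script$allowOverlap) {
    lins <- lapply(masks, function(m)
      .linearIndex(cbind(m$coords, 1L), c(d[1:3], 1L)))
    if (anyDuplicated(unlist(lins)))
      stop("overlapping cell masks in an unscripted collision", call. = FALSE)
  }
  fils <- if (!is.null(script$filaments) && nrow(script$filaments)) {
    lapply(seq_len(nrow(script$filaments)), function(i)
      .filamentVoxels(script$filaments[i, ], d))
  } else list()
  arr <- array(0, dim = d)
  .withSeed(script$seed, {
    nvol <- prod(d[1:3])
    for (t in seq_len(d[4])) {
      # low SNR scales the fluorescent signal, not the background noise
      # floor: relative contrast must drop for detection to fail, since the
      # per-slice mixture threshold adapts to any global intensity scale
      snr <- if (!is.null(script$lowSnr) && t %in% script$lowSnr$t)
        script$lowSnr$factor[match(t, script$lowSnr$t)] else 1
      vol <- array(rbeta(nvol, script$bgShape[1], script$bgShape[2]) * 255,
                   dim = d[1:3])
      for (i in seq_len(nrow(script$cells))) {
        cell <- script$cells[i, ]
        if (t < cell$first_t || t > cell$last_t) next
        m <- masks[[i]]
        u <- rbeta(nrow(m$coords), script$somaShape[1], script$somaShape[2])
        val <- pmin(1, u * snr * (cell$peak / 255) * m$falloff *
                         atten[m$coords[, 3]]) * 255
        vol[m$coords] <- pmax(vol[m$coords], val)
      }
      for (i in seq_along(fils)) {
        pts <- fils[[i]]
        if (!nrow(pts)) next
        u <- rbeta(nrow(pts), script$somaShape[1], script$somaShape[2])
        val <- pmin(1, u * snr * (script$filaments$intensity[i] / 255) *
                         atten[pts[, 3]]) * 255
        vol[pts] <- pmax(vol[pts], val)
      }
      arr[, , , t] <- round(pmin(pmax(vol, 0), 255))
    }
  })
  truth <- list(
    fates = .fatesFromSpans(as.integer(script$cells$first_t),
                            as.integer(script$cells$last_t), d[4]),
    cells = script$cells,
    masks = lapply(masks, `[[`, "coords"))
  list(stack = ImageStack4D(arr, voxelSize = script$voxelSize), truth = truth)
}

#' Ready-made scene scripts used throughout the package
#'
#' \describe{
#'   \item{\code{"multifate"}}{the end-to-end validation scene: a
#'     64 x 64 x 24 x 6 volume with 15 cells, of which 10 are stable
#'     (present throughout), 3 appear at timepoint 4 and 2 disappear after
#'     timepoint 2, plus three dim filaments. The pipeline at default
#'     parameters recovers its fate table exactly.}
#'   \item{\code{"gap"}}{one cell present over timepoints 1-3 with a
#'     low-SNR acquisition at timepoint 2, reproducing the split-component
#'     failure mode that the temporal merge step repairs.}
#'   \item{\code{"empty"}}{pure background, no cells or filaments.}
#' }
#'
#' @param type one of \code{"multifate"}, \code{"gap"}, \code{"empty"}.
#' @param seed integer seed.
#' @return A \code{"SceneScript"}.
#' @export
exampleSceneScript <- function(type = c("multifate", "gap", "empty"),
                               seed = 1L) {
  type <- match.arg(type)
  if (type == "multifate") {
    xy <- c(10, 32, 54)
    slots <- rbind(expand.grid(x = xy, y = xy, z = 7),
                   expand.grid(x = xy[1:3], y = xy[1:2], z = 17))
    # slots 1..9 at z = 7, slots 10..15 at z = 17
    span <- data.frame(
      first_t = c(rep(1L, 6), 1L, 1L, 4L, rep(1L, 4), 4L, 4L),
      last_t  = c(rep(6L, 6), 2L, 2L, 6L, rep(6L, 4), 6L, 6L))
    cells <- data.frame(x = slots$x, y = slots$y, z = slots$z,
                        rxy = 7, rz = 2, first_t = span$first_t,
                        last_t = span$last_t, peak = 600)
    filaments <- data.frame(x1 = c(2, 60, 5), y1 = c(5, 8, 60),
                            z1 = c(12, 12, 13), x2 = c(60, 4, 60),
                            y2 = c(50, 58, 62), z2 = c(12, 13, 12),
                            thickness = 1, intensity = 170)
    sceneScript(dims = c(64, 64, 24, 6), cells = cells,
                filaments = filaments, voxelSize = c(0.5, 0.5, 2),
                seed = seed)
  } else if (type == "gap") {
    cells <- data.frame(x = 24, y = 24, z = 6, rxy = 7, rz = 2,
                        first_t = 1L, last_t = 3L, peak = 600)
    sceneScript(dims = c(48, 48, 12, 3), cells = cells,
                lowSnr = data.frame(t = 2L, factor = 0.05),
                voxelSize = c(0.5, 0.5, 2), seed = seed)
  } else {
    sceneScript(dims = c(48, 48, 12, 3), voxelSize = c(0.5, 0.5, 2),
                seed = seed)
  }
}

#' Random fate scene used for property testing
#'
#' Places up to \code{nCells} cells on a separation-respecting grid of a
#' small volume, with random presence spans, and returns the script.
#'
#' @param seed integer seed (drives slot choice and spans).
#' @param dims integer(4) volume shape; default \code{c(48, 48, 14, 4)}.
#' @param nCells maximum number of cells; default 4.
#' @return A \code{"SceneScript"}.
#' @export
randomFateScript <- function(seed, dims = c(48, 48, 14, 4), nCells = 4L) {
  .withSeed(seed, {
    xy <- c(12, 36)
    slots <- expand.grid(x = xy, y = xy, z = 7)
    n <- sample.int(min(nCells, nrow(slots)), 1)
    pick <- sample.int(nrow(slots), n)
    first <- sample.int(dims[4], n, replace = TRUE)
    len <- sample.int(dims[4], n, replace = TRUE)
    last <- pmin(first + len - 1L, dims[4])
    cells <- data.frame(x = slots$x[pick], y = slots$y[pick],
                        z = slots$z[pick], rxy = 7, rz = 2,
                        first_t = first, last_t = last, peak = 600)
    sceneScript(dims = dims, cells = cells, voxelSize = c(0.5, 0.5, 2),
                seed = seed)
  })
}
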
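#' @import methods
#' @importFrom stats dbeta optim quantile rbeta runif uniroot
NULL

#' Four-dimensional intensity stack
#'
#' Container for a longitudinally registered grayscale volume with axes
#' \code{(x, y, z, t)}. Intensities are bounded in \eqn{[0, 255]} (8-bit
#' native; 16-bit input is linearly rescaled on read). \code{voxelSize}
#' holds the physical voxel extents in micrometres along \code{(x, y, z)}.
#'
#' @slot data 4D numeric array, axes \code{(x, y, z, t)}, values in
#'   \eqn{[0, 255]}.
#' @slot voxelSize numeric(3), micrometres per voxel along x, y, z; all > 0.
#' @export
setClass("ImageStack4D",
  representation(data = "array", voxelSize = "numeric"))

setValidity("ImageStack4D", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (x, y, z, t)")
  if (any(d < 1L)) return("all dimensions must be >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive finite values (x, y, z)")
  r <- range(object@data)
  if (!all(is.finite(r)) || r[1] < 0 || r[2] > 255)
    return("intensities must be finite and within [0, 255]")
  TRUE
})

#' Construct an ImageStack4D
#'
#' @param data 4D numeric array with axes \code{(x, y, z, t)} and values in
#'   \eqn{[0, 255]}.
#' @param voxelSize numeric(3), micrometres per voxel along x, y, z.
#' @return An \linkS4class{ImageStack4D}.
#' @export
ImageStack4D <- function(data, voxelSize = c(1, 1, 1)) {
  new("ImageStack4D", data = data, voxelSize = as.numeric(voxelSize))
}

#' Four-dimensional binary (ROI/background) stack
#'
#' Voxelwise labels after thresholding/denoising: 1 = region of interest,
#' 0 = background. Axes \code{(x, y, z, t)}.
#'
#' @slot data 4D integer array of 0/1 values.
#' @export
setClass("BinaryStack4D", representation(data = "array"))

setValidity("BinaryStack4D", function(object) {
  if (length(dim(object@data)) != 4L) return("data must be a 4D array")
  if (!all(object@data %in% c(0L, 1L))) return("values must be exactly 0 or 1")
  TRUE
})

#' Construct a BinaryStack4D
#'
#' @param data 4D array of 0/1 values, axes \code{(x, y, z, t)}.
#' @return A \linkS4class{BinaryStack4D}.
#' @export
BinaryStack4D <- function(data) {
  storage.mode(data) <- "integer"
  new("BinaryStack4D", data = data)
}

#' Fitted two-component beta mixture for one slice
#'
#' Result of fitting \eqn{p_0 f(y; \alpha_0, \beta_0) + p_1 f(y; \alpha_1,
#' \beta_1)} to the rescaled retained intensities of a single 2D slice.
#' Component 1 is the brighter component (larger mean). When two components
#' are detected the threshold is the crossing point of the weighted
#' densities; otherwise it is a percentile of the retained values.
#'
#' @slot alpha0,beta0 shape parameters of the background component.
#' @slot alpha1,beta1 shape parameters of the bright (ROI) component.
#' @slot p0 mixing proportion of the background component.
#' @slot logLikTrace observed-data log-likelihood per EM iteration.
#' @slot converged logical, EM convergence flag.
#' @slot nComponents 1L or 2L, number of mixture components detected.
#' @slot threshold binarization threshold on the rescaled \eqn{(0,1)} scale.
#' @slot thresholdSource \code{"intersection"} or \code{"fallback_percentile"}.
#' @slot n number of retained values used for fitting.
#' @export
setClass("BetaMixtureFit",
  representation(alpha0 = "numeric", beta0 = "numeric",
                 alpha1 = "numeric", beta1 = "numeric",
                 p0 = "numeric", logLikTrace = "numeric",
                 converged = "logical", nComponents = "integer",
                 threshold = "numeric", thresholdSource = "character",
                 n = "integer"))

#' Tracked cell components of a 4D binary stack
#'
#' Partition of the ROI voxels of a \linkS4class{BinaryStack4D} into
#' connected components under a declared neighborhood kernel. After size
#' filtering, each component is interpreted as one tracked cell; labels are
#' contiguous positive integers numbered by the lexicographic
#' \code{(t, z, y, x)} order of each component's minimal voxel.
#'
#' @slot coords integer matrix with one row per ROI voxel and columns
#'   \code{(x, y, z, t)} (1-based).
#' @slot label integer vector, component label of each voxel row.
#' @slot dims integer(4), dimensions of the originating stack.
#' @slot voxelSize numeric(3), micrometres per voxel along x, y, z.
#' @export
setClass("CellComponentSet",
  representation(coords = "matrix", label = "integer",
                 dims = "integer", voxelSize = "numeric"))

setValidity("CellComponentSet", function(object) {
  if (ncol(object@coords) != 4L) return("coords must have 4 columns (x,y,z,t)")
  if (nrow(object@coords) != length(object@label))
    return("label length must match number of voxels")
  if (length(object@dims) != 4L) return("dims must be integer(4)")
  if (length(object@label) && any(object@label < 1L))
    return("labels must be positive")
  TRUE
})

#' @rdname CellComponentSet-class
#' @param coords integer matrix of ROI voxel coordinates \code{(x, y, z, t)}.
#' @param label integer component label per voxel.
#' @param dims integer(4) stack dimensions.
#' @param voxelSize numeric(3) voxel size in micrometres.
#' @export
CellComponentSet <- function(coords, label, dims, voxelSize = c(1, 1, 1)) {
  coords <- matrix(as.integer(coords), ncol = 4L,
                   dimnames = list(NULL, c("x", "y", "z", "t")))
  new("CellComponentSet", coords = coords, label = as.integer(label),
      dims = as.integer(dims), voxelSize = as.numeric(voxelSize))
}

# ---- generics & accessors ---------------------------------------------------

#' Extract the voxel data array
#' @param x an \linkS4class{ImageStack4D} or \linkS4class{BinaryStack4D}.
#' @return The underlying 4D array.
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' @rdname stackData
#' @export
setMethod("stackData", "ImageStack4D", function(x) x@data)

#' @rdname stackData
#' @export
setMethod("stackData", "BinaryStack4D", function(x) x@data)

#' Physical voxel size in micrometres
#' @param x an object with a voxel-size slot.
#' @return numeric(3), micrometres per voxel along x, y, z.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ImageStack4D", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "CellComponentSet", function(x) x@voxelSize)

#' @export
setMethod("dim", "ImageStack4D", function(x) dim(x@data))

#' @export
setMethod("dim", "BinaryStack4D", function(x) dim(x@data))

#' Number of tracked components
#' @param x a \linkS4class{CellComponentSet}.
#' @return integer, number of distinct components.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "CellComponentSet", function(x) {
  if (!length(x@label)) 0L else max(x@label)
})

#' Component sizes (total 4D voxel counts)
#' @param x a \linkS4class{CellComponentSet}.
#' @return integer vector of per-component voxel counts, indexed by label.
#' @export
setGeneric("cellSizes", function(x) standardGeneric("cellSizes"))

#' @rdname cellSizes
#' @export
setMethod("cellSizes", "CellComponentSet", function(x) {
  if (!length(x@label)) integer(0) else tabulate(x@label, nbins = max(x@label))
})

#' Binarization threshold of a slice fit
#' @param x a \linkS4class{BetaMixtureFit}.
#' @return numeric threshold on the rescaled (0,1) scale.
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname threshold
#' @export
setMethod("threshold", "BetaMixtureFit", function(x) x@threshold)

setMethod("show", "ImageStack4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack4D: %d x %d x %d voxels, %d timepoint(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (um): %.3g x %.3g x %.3g\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryStack4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryStack4D: %d x %d x %d x %d, %d ROI voxel(s)\n",
              d[1], d[2], d[3], d[4], sum(object@data)))
})

setMethod("show", "BetaMixtureFit", function(object) {
  cat(sprintf("BetaMixtureFit (%d value(s), %d component(s)%s)\n",
              object@n, object@nComponents,
              if (object@converged) ", converged" else ""))
  if (object@nComponents == 2L)
    cat(sprintf("  background Beta(%.3g, %.3g)  bright Beta(%.3g, %.3g)  p0 = %.3g\n",
                object@alpha0, object@beta0, object@alpha1, object@beta1,
                object@p0))
  cat(sprintf("  threshold = %.4g (%s)\n", object@threshold,
              object@thresholdSource))
})

setMethod("show", "CellComponentSet", function(object) {
  cat(sprintf("CellComponentSet: %d component(s), %d ROI voxel(s), stack %s\n",
              nCells(object), nrow(object@coords),
              paste(object@dims, collapse = " x ")))
})
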
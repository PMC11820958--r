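# TIFF input/output for 4D stacks.
#
# Internal axis convention: (x, y, z, t), 1-based. TIFF pages are 2D matrices
# in row-major (y, x) orientation as returned by tiff::readTIFF; pages within
# a file are z-planes, ordered z-fastest when a single file holds several
# timepoints (matching ImageJ hyperstack "xyczt" default with one channel).

.readPages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (!is.matrix(p))
      stop("non-grayscale TIFF page in '", path,
           "' (expected a single-channel image)", call. = FALSE)
  }
  pages
}

#' Read a 4D image stack from multi-page TIFF file(s)
#'
#' Reads longitudinally registered grayscale volumes into an
#' \linkS4class{ImageStack4D}. Either one file per timepoint (pages are
#' z-planes) or a single hyperstack file whose pages cycle through z and t.
#' 8-bit data are used natively; 16-bit data are linearly mapped to
#' \eqn{[0, 255]} (with a message reporting the scale factor).
#'
#' @param paths character vector of TIFF paths, ordered by timepoint. With a
#'   single path and \code{nz} set, the file is treated as a hyperstack.
#' @param nz number of z-planes per timepoint; required for a single-file
#'   hyperstack, inferred (= page count) otherwise.
#' @param timeMajor logical; for a single-file hyperstack, \code{FALSE}
#'   (default) means pages are ordered z-fastest (z within t), \code{TRUE}
#'   means t-fastest.
#' @param voxelSize numeric(3), micrometres per voxel along x, y, z.
#' @return An \linkS4class{ImageStack4D}.
#' @seealso [writeLabelStack()], [readLabelStack()]
#' @export
readStack <- function(paths, nz = NULL, timeMajor = FALSE,
                      voxelSize = c(1, 1, 1)) {
  stopifnot(length(paths) >= 1L)
  if (length(paths) == 1L) {
    pages <- .readPages(paths[[1]])
    if (is.null(nz)) nz <- length(pages)
    if (length(pages) %% nz != 0L)
      stop("page count (", length(pages), ") in '", paths[[1]],
           "' is not a multiple of nz = ", nz, call. = FALSE)
    nt <- length(pages) %/% nz
    byT <- if (timeMajor) {
      lapply(seq_len(nt), function(t) pages[seq(t, by = nt, length.out = nz)])
    } else {
      lapply(seq_len(nt), function(t) pages[(t - 1L) * nz + seq_len(nz)])
    }
  } else {
    byT <- lapply(paths, .readPages)
  }
  d0 <- c(dim(byT[[1]][[1]]), length(byT[[1]]))
  for (t in seq_along(byT)) {
    dt <- c(dim(byT[[t]][[1]]), length(byT[[t]]))
    if (!identical(dt, d0))
      stop("timepoint ", t, if (length(paths) > 1)
             paste0(" ('", paths[[t]], "')") else "",
           " has dimensions ", paste(dt, collapse = "x"),
           ", expected ", paste(d0, collapse = "x"), call. = FALSE)
  }
  I <- d0[2]; J <- d0[1]; K <- d0[3]; T <- length(byT)
  arr <- array(0, dim = c(I, J, K, T))
  for (t in seq_len(T)) for (k in seq_len(K))
    arr[, , k, t] <- t(byT[[t]][[k]])
  mx <- max(arr)
  if (mx > 255) {
    arr <- arr * (255 / 65535)
    message("16-bit input linearly rescaled to [0,255] (factor 255/65535)")
  }
  ImageStack4D(arr, voxelSize = voxelSize)
}

.labelBits <- function(maxLab) {
  if (maxLab <= 255) 8L else if (maxLab <= 65535) 16L else 32L
}

#' Write a 4D label (or binary) stack as a multi-page TIFF
#'
#' Labels are nonnegative integers with 0 = background. Bit depth is chosen
#' from the label range (8-bit, 16-bit, or 32-bit float with exact
#' power-of-two scaling for labels up to \eqn{2^{24}}); pages are written
#' z-fastest across timepoints. [readLabelStack()] is the exact inverse.
#'
#' @param labels 4D integer array (axes x, y, z, t), a
#'   \linkS4class{BinaryStack4D}, or a \linkS4class{CellComponentSet} (which
#'   is rendered to a label array first).
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeLabelStack <- function(labels, path) {
  if (methods::is(labels, "CellComponentSet")) labels <- labelArray(labels)
  labels <- .asArray4(labels)
  if (any(labels < 0)) stop("labels must be nonnegative", call. = FALSE)
  d <- dim(labels)
  bits <- .labelBits(max(labels))
  scale <- if (bits == 32L) 2^24 else 2^bits - 1
  pages <- vector("list", d[3] * d[4])
  i <- 0L
  for (t in seq_len(d[4])) for (k in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- t(labels[, , k, t]) / scale
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = bits,
                        compression = "none")
  if (!isTRUE(ok > 0)) stop("failed to write '", path, "'", call. = FALSE)
  invisible(path)
}

#' Read back a label stack written by [writeLabelStack()]
#'
#' @param path TIFF path.
#' @param nz number of z-planes per timepoint; defaults to all pages (single
#'   timepoint).
#' @return 4D integer array (x, y, z, t).
#' @export
readLabelStack <- function(path, nz = NULL) {
  bits <- attr(tiff::readTIFF(path, info = TRUE), "bits.per.sample")
  float <- identical(bits, 32L)
  pages <- if (float) {
    # 32-bit float pages hold label / 2^24 exactly; read them as stored
    p <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(p)) list(p) else p
  } else {
    .readPages(path)
  }
  if (is.null(nz)) nz <- length(pages)
  if (length(pages) %% nz != 0L)
    stop("page count is not a multiple of nz", call. = FALSE)
  nt <- length(pages) %/% nz
  I <- ncol(pages[[1]]); J <- nrow(pages[[1]])
  arr <- array(0L, dim = c(I, J, nz, nt))
  i <- 0L
  for (t in seq_len(nt)) for (k in seq_len(nz)) {
    i <- i + 1L
    p <- pages[[i]]
    if (float) p <- round(p * 2^24)
    arr[, , k, t] <- as.integer(t(p))
  }
  arr
}

#' Render a component set as a 4D label array
#'
#' @param comps a \linkS4class{CellComponentSet}.
#' @return 4D integer array with each ROI voxel set to its component label.
#' @export
labelArray <- function(comps) {
  stopifnot(methods::is(comps, "CellComponentSet"))
  arr <- array(0L, dim = comps@dims)
  if (nrow(comps@coords))
    arr[comps@coords] <- comps@label
  arr
}
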
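# Anisotropic binary median filtering.
#
# Myelin sheaths appear as thin, dim, linear structures; somas are compact
# and roughly spherical. A 3D median over an anisotropic window (wide in-plane,
# narrow in z, default 11 x 11 x 3) removes filaments and impulsive noise
# while preserving soma cores. On a binary image the median is the strict
# majority; borders are zero-padded (outside the volume counts as background,
# which is conservative: no ROI is ever created at borders).

# running window sum of length 2h+1 along dimension d of a 3D array,
# zero-padded, via cumulative sums
.runsum <- function(v, d, h) {
  dm <- dim(v)
  perm <- c(d, setdiff(1:3, d))
  a <- aperm(v, perm)
  n <- dm[d]
  m <- matrix(a, nrow = n)
  cs <- apply(m, 2, cumsum)
  if (n == 1L) cs <- matrix(cs, nrow = 1L)
  hi <- pmin(seq_len(n) + h, n)
  lo <- seq_len(n) - h - 1L
  padded <- rbind(0, cs)
  w <- padded[hi + 1L, , drop = FALSE] - padded[pmax(lo, 0L) + 1L, , drop = FALSE]
  out <- array(w, dim = dm[perm])
  aperm(out, order(perm))
}

.boxsum3 <- function(v, half) {
  for (d in 1:3) if (half[d] > 0L) v <- .runsum(v, d, half[d])
  v
}

#' Binary median filter over a 3D window, per timepoint
#'
#' For each timepoint independently, every voxel becomes the median of the
#' binary values in its centered \code{wx x wy x wz} neighborhood:
#' equivalently, 1 iff more than half of the full (zero-padded) window is 1.
#' Window extents must be odd; with an odd window volume ties are impossible.
#'
#' @param binary a \linkS4class{BinaryStack4D} or 4D 0/1 array.
#' @param window integer(3), odd window extents \code{(wx, wy, wz)};
#'   default \code{c(11, 11, 3)}.
#' @return A \linkS4class{BinaryStack4D}.
#' @export
medianFilter3D <- function(binary, window = c(11, 11, 3)) {
  window <- as.integer(window)
  if (length(window) != 3L || any(window < 1L) || any(window %% 2L == 0L))
    stop("window extents must be three odd integers >= 1", call. = FALSE)
  arr <- .asArray4(binary)
  d <- dim(arr)
  half <- (window - 1L) %/% 2L
  majority <- prod(window) / 2   # strict majority over the padded window
  out <- array(0L, dim = d)
  for (t in seq_len(d[4])) {
    v <- array(as.double(arr[, , , t, drop = TRUE]), dim = d[1:3])
    s <- .boxsum3(v, half)
    out[, , , t] <- as.integer(s > majority)
  }
  BinaryStack4D(out)
}
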
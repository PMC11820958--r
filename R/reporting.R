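# Deliverables: per-cell CSV, per-timepoint fate CSV, and cropped per-cell
# stacks for partially automated visual verification. CSV output uses fixed
# formatting (3-decimal micrometre coordinates, fixed row order) so that
# identical inputs produce byte-identical files.

.fmtNum <- function(x, digits = 3) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

.writeCSV <- function(header, rows, path) {
  con <- file(path, open = "wb")  # binary mode: stable newlines across OSes
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), rows), con, sep = "\n")
  invisible(path)
}

#' Write the per-cell coordinate table as CSV
#'
#' One row per (cell, timepoint with presence): unique cell identifier,
#' voxel count (cell body size), centroid in voxels and micrometres, first
#' and last presence and new/lost flags. Deterministic row order (cell id,
#' then timepoint) and fixed 3-decimal coordinate formatting.
#'
#' @param comps a \linkS4class{CellComponentSet} (or a data.frame from
#'   [cellTable()]).
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeCellTable <- function(comps, path) {
  tab <- if (is.data.frame(comps)) comps else cellTable(comps)
  header <- c("cell_id", "timepoint", "n_voxels", "x_vox", "y_vox", "z_vox",
              "x_um", "y_um", "z_um", "first_t", "last_t", "is_new",
              "is_lost")
  rows <- if (nrow(tab)) {
    paste(tab$cell_id, tab$timepoint, tab$n_voxels,
          .fmtNum(tab$x_vox), .fmtNum(tab$y_vox), .fmtNum(tab$z_vox),
          .fmtNum(tab$x_um), .fmtNum(tab$y_um), .fmtNum(tab$z_um),
          tab$first_t, tab$last_t, tab$is_new, tab$is_lost, sep = ",")
  } else character(0)
  .writeCSV(header, rows, path)
}

#' Write the per-timepoint fate table as CSV
#'
#' One row per timepoint with the number of tracked cells, new cells and
#' lost cells, plus the total as a percentage of the baseline (timepoint 1).
#' With a zero baseline the percentage column is emitted empty, with a
#' warning.
#'
#' @param fates data.frame as returned in \code{classifyFates()$fates}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeFateTable <- function(fates, path) {
  stopifnot(is.data.frame(fates),
            all(c("timepoint", "n_total", "n_new", "n_lost") %in%
                  names(fates)))
  base <- fates$n_total[1]
  if (is.na(base) || base == 0) {
    warning("zero baseline total; percentage column left empty")
    pct <- rep("", nrow(fates))
  } else {
    pct <- .fmtNum(100 * fates$n_total / base, 1)
  }
  rows <- paste(fates$timepoint, fates$n_total, fates$n_new, fates$n_lost,
                pct, sep = ",")
  .writeCSV(c("timepoint", "n_total", "n_new", "n_lost", "pct_of_baseline"),
            rows, path)
}

#' Export cropped per-cell stacks for visual verification
#'
#' For each cell, one multi-page TIFF per timepoint is written, cropped
#' about the cell centroid (for timepoints without presence, the centroid of
#' the nearest timepoint with presence is used, which supports inspection of
#' nascent signal before first detection). Crops are clipped at the volume
#' borders; filenames encode cell id and timepoint.
#'
#' @param stack the original \linkS4class{ImageStack4D}.
#' @param comps a \linkS4class{CellComponentSet}.
#' @param halfwidth integer(3), crop half-extents in voxels per axis
#'   (default \code{c(20, 20, 5)}; crop shape is \code{2*halfwidth + 1}
#'   away from borders).
#' @param dir output directory (created if missing).
#' @return Invisibly, a data.frame manifest (cell_id, timepoint, path,
#'   clipped flag).
#' @export
exportCrops <- function(stack, comps, halfwidth = c(20, 20, 5), dir) {
  stopifnot(methods::is(stack, "ImageStack4D"),
            methods::is(comps, "CellComponentSet"),
            length(halfwidth) == 3L, all(halfwidth >= 0))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  arr <- stackData(stack)
  d <- dim(arr)
  tab <- cellTable(comps)
  manifest <- list()
  for (id in unique(tab$cell_id)) {
    sub <- tab[tab$cell_id == id, , drop = FALSE]
    for (t in seq_len(d[4])) {
      ref <- sub[which.min(abs(sub$timepoint - t)), , drop = FALSE]
      ctr <- round(c(ref$x_vox, ref$y_vox, ref$z_vox))
      lo <- pmax(ctr - halfwidth, 1)
      hi <- pmin(ctr + halfwidth, d[1:3])
      crop <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], t, drop = FALSE]
      path <- file.path(dir, sprintf("cell%04d_t%02d.tif", id, t))
      pages <- lapply(seq_len(dim(crop)[3]), function(k)
        t(crop[, , k, 1]) / 255)
      tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                      compression = "none")
      manifest[[length(manifest) + 1L]] <-
        data.frame(cell_id = id, timepoint = t, path = path,
                   clipped = any(lo != ctr - halfwidth) ||
                             any(hi != ctr + halfwidth))
    }
  }
  invisible(do.call(rbind, manifest))
}
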
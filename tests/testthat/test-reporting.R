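makeTwoCellSet <- function() {
  d <- c(30, 20, 8, 5)
  c1 <- do.call(rbind, lapply(1:5, function(t) cbind(4:6, 5, 3, t)))
  c2 <- do.call(rbind, lapply(2:4, function(t) cbind(20:22, 10, 6, t)))
  CellComponentSet(rbind(c1, c2), rep(1:2, c(nrow(c1), nrow(c2))), d,
                   voxelSize = c(0.5, 0.5, 2))
}

test_that("cell table has one row per (cell, timepoint) and exact um scaling", {
  cc <- makeTwoCellSet()
  tab <- cellTable(cc)
  expect_equal(nrow(tab), 8)                 # 5 + 3 rows
  expect_equal(tab$cell_id, rep(1:2, c(5, 3)))
  expect_equal(tab$x_um, (tab$x_vox - 1) * 0.5)
  expect_equal(tab$z_um, (tab$z_vox - 1) * 2)
  expect_equal(tab$is_new, rep(c(0L, 1L), c(5, 3)))
  expect_equal(tab$is_lost, rep(c(0L, 1L), c(5, 3)))
})

test_that("cell CSV round-trips centroids and sizes exactly", {
  dir <- withr::local_tempdir()
  cc <- makeTwoCellSet()
  p <- file.path(dir, "cells.csv")
  writeCellTable(cc, p)
  back <- read.csv(p)
  tab <- cellTable(cc)
  expect_equal(back$cell_id, tab$cell_id)
  expect_equal(back$n_voxels, tab$n_voxels)
  expect_equal(back$x_vox, round(tab$x_vox, 3))
  expect_equal(back$z_um, round(tab$z_um, 3))
  # empty component set -> header-only file
  empty <- CellComponentSet(matrix(integer(0), 0, 4), integer(0),
                            c(4, 4, 4, 2))
  p0 <- file.path(dir, "empty.csv")
  writeCellTable(empty, p0)
  expect_equal(length(readLines(p0)), 1L)
  expect_equal(nrow(read.csv(p0)), 0L)
})

test_that("fate CSV reports totals, fates and baseline percentages", {
  dir <- withr::local_tempdir()
  # single stable cell: totals all 1, percentages all 100
  ft <- data.frame(timepoint = 1:5, n_total = 1L, n_new = 0L, n_lost = 0L)
  p <- file.path(dir, "fates.csv")
  writeFateTable(ft, p)
  back <- read.csv(p)
  expect_equal(back$n_total, rep(1L, 5))
  expect_equal(back$pct_of_baseline, rep(100, 5))
  # conservation columns are mutually consistent in a real table
  cc <- makeTwoCellSet()
  cf <- classifyFates(cc)
  writeFateTable(cf$fates, p)
  back2 <- read.csv(p)
  expect_equal(diff(back2$n_total), head(back2$n_new - back2$n_lost, -1))
  # zero baseline leaves percentages empty with a warning
  ft0 <- data.frame(timepoint = 1:3, n_total = c(0L, 1L, 1L),
                    n_new = c(1L, 0L, 0L), n_lost = 0L)
  expect_warning(writeFateTable(ft0, p), "baseline")
  expect_true(all(is.na(read.csv(p)$pct_of_baseline)))
})

test_that("CSV output is byte-identical across repeated writes", {
  dir <- withr::local_tempdir()
  cc <- makeTwoCellSet()
  p1 <- file.path(dir, "a.csv"); p2 <- file.path(dir, "b.csv")
  writeCellTable(cc, p1); writeCellTable(cc, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("crops are centered, clipped at borders, and contain the cell", {
  dir <- withr::local_tempdir()
  scene <- generateScene(exampleSceneScript("gap", seed = 2))
  res <- runPipeline(runConfig(outputDir = tempfile(), seed = 1),
                     stack = scene$stack, writeOutputs = FALSE)
  man <- exportCrops(scene$stack, res$components, halfwidth = c(10, 10, 3),
                     dir = dir)
  # one file per (cell, timepoint), including absent timepoints
  expect_equal(nrow(man), nCells(res$components) * dim(scene$stack)[4])
  expect_true(all(file.exists(man$path)))
  crop <- readLabelStack(man$path[1])
  expect_equal(dim(crop)[1:2], c(21L, 21L))  # 2*10+1 in x and y
  # the crop contains the scripted cell center voxel intensity region
  expect_gt(max(crop), 200)
  # a cell at a corner is clipped to the volume
  d <- c(12, 12, 6, 1)
  co <- cbind(1:3, 1, 1, 1)
  cc <- CellComponentSet(co, rep(1L, 3), d)
  stk <- ImageStack4D(array(100, d))
  man2 <- exportCrops(stk, cc, halfwidth = c(5, 5, 2), dir = dir)
  crop2 <- readLabelStack(man2$path[1])
  expect_true(all(dim(crop2)[1:2] < c(11L, 11L)))
  expect_true(man2$clipped[1])
})
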
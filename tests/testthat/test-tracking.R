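test_that("4D labeling matches a BFS flood-fill oracle on random stacks", {
  set.seed(20)
  for (rep in 1:10) {
    d <- c(sample(6:15, 1), sample(6:15, 1), sample(3:8, 1), sample(2:5, 1))
    arr <- array(as.integer(runif(prod(d)) < 0.2), d)
    got <- labelComponents4D(arr)
    oracle <- bfsComponents4(arr)
    expect_identical(canonLabels(got@label), canonLabels(oracle))
  }
})

test_that("kernel adjacency follows the 80-neighborhood definition", {
  b <- array(0L, c(10, 10, 10, 6))
  b[1, 1, 1, 1] <- 1L; b[6, 6, 6, 6] <- 1L
  expect_equal(nCells(labelComponents4D(b)), 2L)
  b2 <- array(0L, c(4, 4, 4, 4))
  b2[2, 2, 2, 2] <- 1L; b2[3, 3, 3, 3] <- 1L  # offset (+1,+1,+1,+1)
  expect_equal(nCells(labelComponents4D(b2)), 1L)
  expect_error(labelComponents4D(b2, kernel = c(2, 3, 3, 3)), "odd")
})

test_that("labels are deterministic and ordered by minimal (t,z,y,x) voxel", {
  b <- array(0L, c(8, 8, 4, 3))
  b[5:6, 5:6, 2, 2] <- 1L   # later timepoint
  b[2:3, 2:3, 1, 1] <- 1L   # earliest voxel -> label 1
  cc <- labelComponents4D(b)
  expect_equal(nCells(cc), 2L)
  first <- cc@coords[cc@label == 1L, , drop = FALSE]
  expect_true(all(first[, 4] == 1L))
})

test_that("split components merge across a low-signal gap, transitively", {
  # one sphere present at t = 1 and t = 3, absent at t = 2
  d <- c(15, 15, 9, 3)
  sph <- sphereVolume(d[1:3], c(8, 8, 5), 3.2)
  b <- array(0L, d)
  b[, , , 1] <- sph; b[, , , 3] <- sph
  cc <- labelComponents4D(b)
  expect_equal(nCells(cc), 2L)
  # halfwidth 0 is the identity
  same <- mergeSplitComponents(cc, halfwidth = c(0, 0, 0))
  expect_identical(same@label, cc@label)
  # default window spans the gap -> one component
  merged <- mergeSplitComponents(cc)
  expect_equal(nCells(merged), 1L)
  # two spheres 50 voxels apart stay distinct under halfwidth 2
  d2 <- c(70, 15, 9, 2)
  b2 <- array(0L, d2)
  b2[, , , 1] <- sphereVolume(d2[1:3], c(8, 8, 5), 3) +
    sphereVolume(d2[1:3], c(58, 8, 5), 3)
  cc2 <- mergeSplitComponents(labelComponents4D(b2), halfwidth = c(2, 2, 2))
  expect_equal(nCells(cc2), 2L)
})

test_that("merging is order-independent", {
  set.seed(21)
  arr <- array(as.integer(runif(12 * 12 * 6 * 4) < 0.1), c(12, 12, 6, 4))
  cc <- labelComponents4D(arr)
  m1 <- mergeSplitComponents(cc, halfwidth = c(2, 2, 2), gap = 1)
  # permute voxel rows (processing order) and re-merge
  set.seed(22)
  perm <- sample(nrow(cc@coords))
  ccP <- CellComponentSet(cc@coords[perm, ], cc@label[perm], cc@dims,
                          cc@voxelSize)
  m2 <- mergeSplitComponents(ccP, halfwidth = c(2, 2, 2), gap = 1)
  ord1 <- order(somatrack:::.linearIndex(m1@coords, m1@dims))
  ord2 <- order(somatrack:::.linearIndex(m2@coords, m2@dims))
  expect_identical(m1@label[ord1], m2@label[ord2])
})

test_that("size filter keeps 30-voxel components and drops 29-voxel ones", {
  d <- c(40, 10, 10, 1)
  co29 <- cbind(2:30, 5, 5, 1)            # 29 voxels in a row
  co30 <- cbind(2:31, 8, 8, 1)            # 30 voxels
  cc <- CellComponentSet(rbind(co29, co30),
                         rep(1:2, c(29, 30)), d)
  kept <- filterSmallComponents(cc, minSize = 30)
  expect_equal(nCells(kept), 1L)
  expect_equal(nrow(kept@coords), 30L)
  expect_true(all(kept@coords[, 2] == 8L))
  # minSize 1 is the identity
  expect_identical(filterSmallComponents(cc, 1)@label, cc@label)
})

test_that("size filter equals a brute-force census and never splits components", {
  set.seed(23)
  arr <- array(as.integer(runif(14 * 14 * 6 * 3) < 0.15), c(14, 14, 6, 3))
  cc <- labelComponents4D(arr)
  for (minSize in c(2, 5, 10)) {
    kept <- filterSmallComponents(cc, minSize)
    sizes <- tabulate(cc@label)
    expect_equal(nCells(kept), sum(sizes >= minSize))
    expect_equal(nrow(kept@coords), sum(sizes[sizes >= minSize]))
    expect_equal(sum(cellSizes(kept)), nrow(kept@coords))
  }
})

test_that("fate classification follows the reported-at-previous-timepoint convention", {
  d <- c(20, 10, 6, 9)
  # one component present at every t: never new or lost
  stable <- do.call(rbind, lapply(1:9, function(t) cbind(2:5, 2, 2, t)))
  # one present only at t in {3,4,5}: new at 2, lost at 5
  mid <- do.call(rbind, lapply(3:5, function(t) cbind(12:15, 8, 4, t)))
  cc <- CellComponentSet(rbind(stable, mid),
                         rep(1:2, c(nrow(stable), nrow(mid))), d)
  cf <- classifyFates(cc)
  expect_equal(cf$fates$n_total, c(1, 1, 2, 2, 2, 1, 1, 1, 1))
  expect_equal(cf$fates$n_new[2], 1)
  expect_equal(sum(cf$fates$n_new), 1)
  expect_equal(cf$fates$n_lost[5], 1)
  expect_equal(sum(cf$fates$n_lost), 1)
  expect_equal(cf$cells$first_t, c(1L, 3L))
  expect_equal(cf$cells$last_t, c(9L, 5L))
  # conservation identity
  ft <- cf$fates
  expect_equal(ft$n_total[-1],
               head(ft$n_total + ft$n_new - ft$n_lost, -1))
})

test_that("depth stratification partitions cells and preserves totals", {
  d <- c(10, 10, 40, 4)
  vs <- c(1, 1, 10)  # slice z maps to depth (z-1)*10 um
  mk <- function(zc, first, last, xoff)
    do.call(rbind, lapply(first:last, function(t) cbind(xoff + 0:2, 5, zc, t)))
  coords <- rbind(mk(6, 1, 4, 1),    # depth 50 -> [0,100)
                  mk(16, 1, 2, 5),   # depth 150 -> [100,200)
                  mk(26, 2, 4, 1))   # depth 250 -> [200,300)
  cc <- CellComponentSet(coords, rep(1:3, c(12, 6, 9)), d, voxelSize = vs)
  st <- stratifyByDepth(cc, binEdges = c(0, 100, 200, 300))
  expect_named(st$bins, c("[0,100)", "[100,200)", "[200,300)"))
  expect_equal(st$assignment$bin, c("[0,100)", "[100,200)", "[200,300)"))
  # per-bin tables sum to the unstratified table
  tot <- Reduce(`+`, lapply(st$bins, function(b)
    as.matrix(b[, c("n_total", "n_new", "n_lost")])))
  un <- as.matrix(classifyFates(cc)$fates[, c("n_total", "n_new", "n_lost")])
  expect_equal(tot, un)
  # a cell deeper than the last edge lands in the overflow bin with warning
  cc2 <- CellComponentSet(mk(36, 1, 1, 1), rep(1L, 3), d, voxelSize = vs)
  expect_warning(st2 <- stratifyByDepth(cc2, binEdges = c(0, 100, 200, 300)),
                 "overflow")
  expect_equal(st2$bins$overflow$n_total[1], 1)
})
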
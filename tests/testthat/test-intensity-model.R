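ns <- asNamespace("somatrack")

test_that("premask retains exactly the pixels at or above the percentile value", {
  # oracle: sort and index
  set.seed(1)
  sl <- matrix(sample(1:100), 10, 10)
  obs <- premaskSlice(sl, 99)
  cutoff <- sort(as.vector(sl))[ceiling(0.99 * 100)]
  expect_identical(obs$mask, sl >= cutoff)
  expect_equal(sum(obs$mask), sum(sl >= cutoff))
  # percentile 0 retains every pixel
  obs0 <- premaskSlice(sl, 0)
  expect_true(all(obs0$mask))
  expect_equal(length(obs0$values), 100)
  # retained values are rescaled into the clamped unit interval
  expect_true(all(obs0$values >= 1e-6 & obs0$values <= 1 - 1e-6))
  expect_equal(min(obs0$values), 1e-6)
  expect_equal(max(obs0$values), 1 - 1e-6)
})

test_that("a constant slice is flagged degenerate", {
  obs <- premaskSlice(matrix(7, 5, 5))
  expect_true(obs$degenerate)
  expect_false(any(obs$mask))
})

test_that("E-step responsibilities match the posterior-ratio formula", {
  eStep <- ns$.eStep
  # identical components: posterior equals the prior
  th <- list(a0 = 2, b0 = 5, a1 = 2, b1 = 5, p0 = 0.3)
  y <- seq(0.05, 0.95, by = 0.05)
  expect_equal(eStep(y, th), rep(0.7, length(y)))
  # p0 = 1: responsibility for class 1 is zero
  th1 <- list(a0 = 2, b0 = 5, a1 = 5, b1 = 2, p0 = 1)
  expect_equal(eStep(y, th1), rep(0, length(y)))
  # random theta: brute-force direct ratio
  set.seed(4)
  for (rep in 1:5) {
    th <- list(a0 = runif(1, 0.5, 6), b0 = runif(1, 0.5, 6),
               a1 = runif(1, 0.5, 6), b1 = runif(1, 0.5, 6),
               p0 = runif(1, 0.1, 0.9))
    y <- runif(50, 0.01, 0.99)
    direct <- (1 - th$p0) * dbeta(y, th$a1, th$b1) /
      (th$p0 * dbeta(y, th$a0, th$b0) + (1 - th$p0) * dbeta(y, th$a1, th$b1))
    expect_equal(eStep(y, th), direct, tolerance = 1e-12)
  }
})

test_that("M-step with hard assignments equals the per-group beta MLE", {
  skip_if_not_installed("fitdistrplus")
  mStep <- ns$.mStep
  set.seed(5)
  y <- c(rbeta(400, 2, 7), rbeta(300, 7, 2.5))
  r1 <- rep(c(0, 1), c(400, 300))
  th0 <- list(a0 = 1, b0 = 1, a1 = 1, b1 = 1, p0 = 0.5)
  out <- mStep(y, r1, th0)$theta
  # independent oracle: single-sample beta MLE of each assigned group
  f0 <- fitdistrplus::fitdist(y[r1 == 0], "beta")
  f1 <- fitdistrplus::fitdist(y[r1 == 1], "beta")
  expect_equal(out$a0, unname(f0$estimate["shape1"]), tolerance = 1e-3)
  expect_equal(out$b0, unname(f0$estimate["shape2"]), tolerance = 1e-3)
  expect_equal(out$a1, unname(f1$estimate["shape1"]), tolerance = 1e-3)
  expect_equal(out$b1, unname(f1$estimate["shape2"]), tolerance = 1e-3)
  expect_equal(out$p0, 400 / 700)
})

test_that("M-step p0 update equals the mean class-0 responsibility", {
  mStep <- ns$.mStep
  set.seed(6)
  y <- runif(200, 0.05, 0.95)
  r1 <- runif(200)
  out <- mStep(y, r1, list(a0 = 2, b0 = 2, a1 = 3, b1 = 3, p0 = 0.5))$theta
  expect_equal(out$p0, mean(1 - r1))
  # symmetric responsibilities with identical inits give identical updates
  out2 <- mStep(y, rep(0.5, 200),
                list(a0 = 2, b0 = 4, a1 = 2, b1 = 4, p0 = 0.5))$theta
  expect_equal(out2$a0, out2$a1)
  expect_equal(out2$b0, out2$b1)
})

test_that("EM recovers a known two-beta mixture with a nondecreasing loglik", {
  errs <- sapply(1:5, function(s) {
    set.seed(s)
    y <- c(rbeta(2000, 2, 8), rbeta(2000, 8, 2))
    f <- fitBetaMixEM(y, seed = s)
    expect_true(all(diff(f@logLikTrace) > -1e-8))
    expect_identical(f@nComponents, 2L)
    c(abs(f@p0 - 0.5),
      abs(f@alpha0 / (f@alpha0 + f@beta0) - 0.2),
      abs(f@alpha1 / (f@alpha1 + f@beta1) - 0.8))
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.02)
  expect_lt(median(errs[3, ]), 0.02)
})

test_that("unimodal data collapses to one component with percentile fallback", {
  for (s in 1:3) {
    set.seed(s)
    y <- rbeta(3000, 3, 3)
    f <- fitBetaMixEM(y, seed = s)
    expect_identical(f@nComponents, 1L)
    expect_identical(f@thresholdSource, "fallback_percentile")
    # fallback is the empirical 80th percentile of the values
    expect_equal(f@threshold, sort(y)[ceiling(0.8 * length(y))])
  }
})

test_that("too few retained values trigger the fallback threshold", {
  y <- runif(20, 0.2, 0.8)
  f <- fitBetaMixEM(y, seed = 1, minValues = 50)
  expect_identical(f@nComponents, 1L)
  expect_identical(f@thresholdSource, "fallback_percentile")
})

test_that("the intersection threshold is a root of the weighted density difference", {
  # mirror-symmetric mixture crosses at exactly 1/2
  thr <- intersectThreshold(list(a0 = 2, b0 = 5, a1 = 5, b1 = 2, p0 = 0.5))
  expect_equal(thr, 0.5, tolerance = 1e-6)
  # asymmetric weights: compare with a dense grid-search oracle
  th <- list(a0 = 2, b0 = 8, a1 = 8, b1 = 2, p0 = 0.7)
  g <- seq(1e-6, 1 - 1e-6, length.out = 1e6 + 1)
  oracle <- g[which.min(abs(th$p0 * dbeta(g, th$a0, th$b0) -
                              (1 - th$p0) * dbeta(g, th$a1, th$b1)))]
  expect_equal(intersectThreshold(th), oracle, tolerance = 1e-5)
  # residual is tiny at the returned root for random parameter draws
  set.seed(7)
  for (rep in 1:20) {
    th <- list(a0 = runif(1, 1, 6), b0 = runif(1, 3, 10),
               a1 = runif(1, 3, 10), b1 = runif(1, 1, 6),
               p0 = runif(1, 0.2, 0.8))
    tau <- intersectThreshold(th)
    if (is.na(tau)) next
    expect_lt(abs(th$p0 * dbeta(tau, th$a0, th$b0) -
                    (1 - th$p0) * dbeta(tau, th$a1, th$b1)), 1e-6)
  }
})

test_that("the threshold grows monotonically as the background weight grows", {
  p0s <- seq(0.3, 0.95, by = 0.05)
  taus <- sapply(p0s, function(p)
    intersectThreshold(list(a0 = 2, b0 = 8, a1 = 8, b1 = 2, p0 = p)))
  expect_true(all(diff(taus) > 0))
})

test_that("binarization labels disk interiors ROI and background clean", {
  fx <- diskSlice()
  stk <- ImageStack4D(array(fx$slice, c(64, 64, 1, 1)))
  out <- binarizeStack(stk, premaskPercentile = 0, seed = 4)
  expect_identical(out$diagnostics$nComponents, 2L)
  roi <- stackData(out$binary)[, , 1, 1]
  interior <- rep(FALSE, nrow(fx$xy))
  far <- !fx$diskMask
  for (cc in fx$centers) {
    dist <- sqrt((fx$xy$x - cc[1])^2 + (fx$xy$y - cc[2])^2)
    interior <- interior | dist <= fx$radius - 2
    far <- far & dist > fx$radius + 4
  }
  expect_gte(mean(roi[as.matrix(fx$xy[interior, ])]), 0.99)
  expect_lte(mean(roi[as.matrix(fx$xy[far, ])]), 0.01)
})

test_that("slice-wise binarization commutes with z-permutation and handles all-zero stacks", {
  scene <- generateScene(exampleSceneScript("gap", seed = 5))
  a <- stackData(scene$stack)
  set.seed(8)
  perm <- sample(dim(a)[3])
  b1 <- stackData(binarizeStack(ImageStack4D(a), seed = 3)$binary)
  b2 <- stackData(binarizeStack(ImageStack4D(a[, , perm, , drop = FALSE]),
                                seed = 3)$binary)
  expect_identical(b1[, , perm, , drop = FALSE], b2)
  # an all-zero stack is entirely background, every slice degenerate
  z <- binarizeStack(ImageStack4D(array(0, c(8, 8, 2, 2))), seed = 1)
  expect_equal(sum(stackData(z$binary)), 0)
  expect_true(all(z$diagnostics$thresholdSource == "degenerate"))
})
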
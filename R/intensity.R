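# Per-slice intensity model: two-component beta mixture fitted by EM.
#
# Each 2D slice (fixed z, t) is treated independently so that the model
# adapts to depth-dependent attenuation. Pixels below a high percentile of
# the slice are pre-masked as background (most pixels are background in
# sparse fluorescence images); the retained intensities are min-max rescaled
# to (0, 1) and modeled as p0*Beta(a0, b0) + p1*Beta(a1, b1). The threshold
# is the crossing point of the weighted component densities, or a percentile
# of the retained values when only one component is detected.

#' Pre-mask and rescale one 2D slice
#'
#' Pixels strictly below the \code{premaskPercentile}-th empirical percentile
#' of the slice are labeled background and excluded from fitting. Retained
#' intensities are min-max rescaled to \eqn{[0, 1]} and clamped to
#' \eqn{[\epsilon, 1 - \epsilon]}.
#'
#' @param slice 2D numeric matrix of raw intensities in \eqn{[0, 255]}.
#' @param premaskPercentile percentile in \eqn{[0, 100]}; default 99 (the
#'   astrocyte preset uses 98).
#' @param eps clamping margin; default \code{1e-6}.
#' @return A list with elements \code{values} (rescaled retained
#'   intensities), \code{mask} (logical matrix of retained pixels),
#'   \code{rescaled} (numeric matrix of rescaled values, 0 where masked),
#'   \code{degenerate} (TRUE when the whole slice is constant) and
#'   \code{constant} (TRUE when the retained values have zero spread).
#' @export
premaskSlice <- function(slice, premaskPercentile = 99, eps = 1e-6) {
  stopifnot(is.matrix(slice), premaskPercentile >= 0, premaskPercentile <= 100)
  v <- as.vector(slice)
  if (diff(range(v)) == 0) {
    return(list(values = numeric(0),
                mask = matrix(FALSE, nrow(slice), ncol(slice)),
                rescaled = matrix(0, nrow(slice), ncol(slice)),
                degenerate = TRUE, constant = TRUE))
  }
  q <- .percentile(v, premaskPercentile)
  mask <- slice >= q
  raw <- slice[mask]
  rng <- range(raw)
  rescaled <- matrix(0, nrow(slice), ncol(slice))
  if (diff(rng) == 0) {
    # heavily saturated retained set (e.g. bright somas clipped at 255):
    # all retained values map to the same point
    vals <- rep(0.5, length(raw))
    constant <- TRUE
  } else {
    vals <- .clamp01((raw - rng[1]) / diff(rng), eps)
    constant <- FALSE
  }
  rescaled[mask] <- vals
  list(values = vals, mask = mask, rescaled = rescaled,
       degenerate = FALSE, constant = constant)
}

# log joint weights log(p_z f_z(y)) and derived quantities
.mixLogDens <- function(y, theta) {
  l0 <- log(theta$p0) + dbeta(y, theta$a0, theta$b0, log = TRUE)
  l1 <- log1p(-theta$p0) + dbeta(y, theta$a1, theta$b1, log = TRUE)
  m <- pmax(l0, l1)
  den <- m + log(exp(l0 - m) + exp(l1 - m))
  list(l0 = l0, l1 = l1, den = den)
}

# E-step: posterior responsibility for the bright component (class 1),
# r1(y) = p1 f1(y) / (p0 f0(y) + p1 f1(y)), computed in log space
.eStep <- function(y, theta) {
  ld <- .mixLogDens(y, theta)
  r1 <- exp(ld$l1 - ld$den)
  bad <- !is.finite(r1)
  if (any(bad)) {
    warning("degenerate densities in E-step; responsibilities set to prior")
    r1[bad] <- 1 - theta$p0
  }
  r1
}

# observed-data log-likelihood
.obsLogLik <- function(y, theta) sum(.mixLogDens(y, theta)$den)

# weighted beta maximum-likelihood via sufficient statistics
# (S1 = sum w log y, S2 = sum w log(1-y), W = sum w); optimized over
# (log alpha, log beta) with analytic gradient and box constraints
.wbetaMLE <- function(S1, S2, W, init = c(1, 1), bounds = c(1e-3, 1e3)) {
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -((a - 1) * S1 + (b - 1) * S2 - W * lbeta(a, b))
  }
  grad <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    dab <- digamma(a + b)
    c(-a * (S1 - W * (digamma(a) - dab)),
      -b * (S2 - W * (digamma(b) - dab)))
  }
  init <- pmin(pmax(init, bounds[1]), bounds[2])
  fit <- tryCatch(
    optim(log(init), nll, grad, method = "L-BFGS-B",
          lower = log(bounds[1]), upper = log(bounds[2])),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$par)) || fit$value > nll(log(init)))
    return(list(shape = init, ok = FALSE))
  list(shape = exp(fit$par), ok = TRUE)
}

# method-of-moments beta estimate, used to seed the first M-step
.betaMoments <- function(y, w) {
  W <- sum(w)
  m <- sum(w * y) / W
  v <- sum(w * (y - m)^2) / W
  v <- max(v, 1e-8)
  s <- max(m * (1 - m) / v - 1, 1e-3)
  c(max(m * s, 1e-3), max((1 - m) * s, 1e-3))
}

# M-step: p0 is the mean class-0 responsibility (closed form); the shape
# parameters maximize the weighted beta log-likelihood per component
.mStep <- function(y, r1, theta) {
  p0 <- mean(1 - r1)
  p0 <- min(max(p0, 1e-8), 1 - 1e-8)
  ly <- log(y); l1y <- log1p(-y)
  w0 <- 1 - r1
  f0 <- .wbetaMLE(sum(w0 * ly), sum(w0 * l1y), sum(w0),
                  init = c(theta$a0, theta$b0))
  f1 <- .wbetaMLE(sum(r1 * ly), sum(r1 * l1y), sum(r1),
                  init = c(theta$a1, theta$b1))
  list(theta = list(a0 = f0$shape[1], b0 = f0$shape[2],
                    a1 = f1$shape[1], b1 = f1$shape[2], p0 = p0),
       ok = f0$ok && f1$ok)
}

.fallbackFit <- function(values, fallbackPercentile, n) {
  thr <- if (length(values)) .percentile(values, fallbackPercentile) else 1
  new("BetaMixtureFit", alpha0 = NA_real_, beta0 = NA_real_,
      alpha1 = NA_real_, beta1 = NA_real_, p0 = NA_real_,
      logLikTrace = numeric(0), converged = FALSE, nComponents = 1L,
      threshold = thr, thresholdSource = "fallback_percentile",
      n = as.integer(n))
}

# EM iteration from a given starting point
.emIterate <- function(y, theta, maxIter, tol) {
  trace <- numeric(0)
  converged <- FALSE
  for (r in seq_len(maxIter)) {
    r1 <- .eStep(y, theta)
    ll <- .obsLogLik(y, theta)
    trace <- c(trace, ll)
    if (r > 1L && abs(ll - trace[r - 1L]) < tol) {
      converged <- TRUE
      break
    }
    theta <- .mStep(y, r1, theta)$theta
  }
  list(theta = theta, trace = trace, converged = converged,
       logLik = trace[length(trace)])
}

.thetaFromAssignment <- function(y, z1) {
  if (sum(z1) == 0L || sum(z1) == length(y))
    z1[sample.int(length(y), 1)] <- 1L - z1[1]
  s0 <- .betaMoments(y, 1 - z1)
  s1 <- .betaMoments(y, z1)
  list(a0 = s0[1], b0 = s0[2], a1 = s1[1], b1 = s1[2], p0 = mean(z1 == 0L))
}

# Multi-start EM. The purely random class assignment is symmetric in
# distribution between the two components, and the EM map has an attracting
# fixed point where both components equal the pooled single-beta fit; from
# an exchangeable start the iteration can settle there even for strongly
# bimodal data. A second start that splits the data at a random pivot value
# breaks the exchangeability; the run with the higher final observed
# log-likelihood wins.
.runEM <- function(y, seed, maxIter, tol) {
  n <- length(y)
  .withSeed(seed, {
    zRand <- as.integer(runif(n) < 0.5)
    pivot <- y[sample.int(n, 1)]
    runs <- list(
      .emIterate(y, .thetaFromAssignment(y, zRand), maxIter, tol),
      .emIterate(y, .thetaFromAssignment(y, as.integer(y > pivot)),
                 maxIter, tol))
    lls <- vapply(runs, function(r)
      if (is.finite(r$logLik)) r$logLik else -Inf, numeric(1))
    runs[[which.max(lls)]]
  })
}

# single-beta maximum likelihood fit (no mixture), for collapse detection
.singleBetaLogLik <- function(y) {
  fit <- .wbetaMLE(sum(log(y)), sum(log1p(-y)), length(y),
                   init = .betaMoments(y, rep(1, length(y))))
  sum(dbeta(y, fit$shape[1], fit$shape[2], log = TRUE))
}

#' Fit a two-component beta mixture to slice intensities by EM
#'
#' Two seeded starts are used: a purely random class assignment, and a split
#' of the data at a random pivot value (the random assignment alone is
#' exchangeable between components and can settle on the attracting fixed
#' point where both components equal the pooled single-beta fit; the pivot
#' start breaks that symmetry). From each start, E- and M-steps alternate
#' until the observed-data log-likelihood changes by less than \code{tol}
#' or \code{maxIter} is reached, and the run with the higher final
#' log-likelihood wins. After fitting, components are relabeled so component
#' 1 is the brighter one. A single-component collapse is declared when the
#' fitted mixing proportion leaves \eqn{[\delta, 1-\delta]}, the component
#' means differ by less than \code{collapseMeanDiff}, the EM fails to
#' converge from two different seeds, or a BIC comparison against the
#' single-beta maximum-likelihood fit prefers one component; the threshold
#' then falls back to the \code{fallbackPercentile}-th percentile of the
#' retained values.
#'
#' @param values numeric vector of rescaled intensities in (0, 1), as
#'   produced by [premaskSlice()].
#' @param seed integer seed for the random initialization.
#' @param maxIter maximum EM iterations (default 200).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6).
#' @param fallbackPercentile percentile used when only one component is
#'   detected; default 80 (the astrocyte preset uses 70).
#' @param minValues minimum number of retained values required to attempt a
#'   fit (default 50).
#' @param collapseP0 collapse margin \eqn{\delta} on the mixing proportion
#'   (default 0.02).
#' @param collapseMeanDiff minimum separation of component means
#'   (default 0.02).
#' @return A \linkS4class{BetaMixtureFit}.
#' @examples
#' set.seed(1)
#' y <- c(rbeta(500, 2, 8), rbeta(500, 8, 2))
#' fitBetaMixEM(y, seed = 1)
#' @export
fitBetaMixEM <- function(values, seed = 1L, maxIter = 200L, tol = 1e-6,
                         fallbackPercentile = 80, minValues = 50L,
                         collapseP0 = 0.02, collapseMeanDiff = 0.02) {
  n <- length(values)
  if (n < minValues || diff(range(values)) == 0)
    return(.fallbackFit(values, fallbackPercentile, n))
  stopifnot(all(values > 0 & values < 1))
  run <- .runEM(values, seed, maxIter, tol)
  if (!run$converged) {
    run2 <- .runEM(values, .sliceSeed(seed, 977L, 997L), maxIter, tol)
    if (run2$converged) run <- run2
  }
  theta <- run$theta
  m0 <- theta$a0 / (theta$a0 + theta$b0)
  m1 <- theta$a1 / (theta$a1 + theta$b1)
  if (m0 > m1) {  # relabel: component 1 is the brighter component
    theta <- list(a0 = theta$a1, b0 = theta$b1, a1 = theta$a0, b1 = theta$b0,
                  p0 = 1 - theta$p0)
    tmp <- m0; m0 <- m1; m1 <- tmp
  }
  # collapse to one component when the second component is not supported:
  # extreme mixing proportion, indistinguishable means, non-convergence, or
  # a BIC comparison against the single-beta fit (3 extra parameters)
  # preferring the simpler model
  bicCollapse <- 2 * (run$logLik - .singleBetaLogLik(values)) < 3 * log(n)
  collapsed <- !run$converged ||
    theta$p0 < collapseP0 || theta$p0 > 1 - collapseP0 ||
    (m1 - m0) < collapseMeanDiff || bicCollapse
  fit <- new("BetaMixtureFit",
             alpha0 = theta$a0, beta0 = theta$b0,
             alpha1 = theta$a1, beta1 = theta$b1, p0 = theta$p0,
             logLikTrace = run$trace, converged = run$converged,
             nComponents = if (collapsed) 1L else 2L,
             threshold = NA_real_, thresholdSource = "", n = as.integer(n))
  if (!collapsed) {
    thr <- intersectThreshold(fit)
    if (is.na(thr)) {
      collapsed <- TRUE
    } else {
      fit@threshold <- thr
      fit@thresholdSource <- "intersection"
    }
  }
  if (collapsed) {
    fit@nComponents <- 1L
    fit@threshold <- .percentile(values, fallbackPercentile)
    fit@thresholdSource <- "fallback_percentile"
  }
  fit
}

#' Crossing point of the weighted mixture densities
#'
#' Finds the root of \eqn{g(y) = p_0 f_0(y) - p_1 f_1(y)} between the two
#' component means by bracketed root finding on the log-density difference.
#' If several sign changes exist in that interval, the one nearest the
#' midpoint of the means is used. Returns \code{NA} (caller falls back to a
#' percentile threshold) when no sign change exists between the means.
#'
#' @param fit a \linkS4class{BetaMixtureFit} with two detected components,
#'   or a list with elements \code{a0, b0, a1, b1, p0}.
#' @param gridN number of grid points used to bracket sign changes.
#' @return The threshold in (0, 1), or \code{NA_real_}.
#' @export
intersectThreshold <- function(fit, gridN = 512L) {
  th <- if (methods::is(fit, "BetaMixtureFit"))
    list(a0 = fit@alpha0, b0 = fit@beta0, a1 = fit@alpha1, b1 = fit@beta1,
         p0 = fit@p0)
  else fit
  stopifnot(all(vapply(th, is.finite, logical(1))))
  h <- function(y)
    log(th$p0) + dbeta(y, th$a0, th$b0, log = TRUE) -
      log1p(-th$p0) - dbeta(y, th$a1, th$b1, log = TRUE)
  m0 <- th$a0 / (th$a0 + th$b0)
  m1 <- th$a1 / (th$a1 + th$b1)
  lo <- min(m0, m1); hi <- max(m0, m1)
  if (hi - lo < 1e-10) return(NA_real_)
  grid <- seq(lo, hi, length.out = gridN)
  hv <- h(grid)
  sgn <- sign(hv)
  flips <- which(sgn[-1] * sgn[-gridN] < 0)
  exact <- which(hv == 0)
  if (!length(flips) && !length(exact)) return(NA_real_)
  mid <- (lo + hi) / 2
  cand <- c(grid[exact],
            vapply(flips, function(i) {
              uniroot(h, c(grid[i], grid[i + 1]), tol = 1e-12)$root
            }, numeric(1)))
  cand[which.min(abs(cand - mid))]
}

#' Binarize a 4D stack slice-by-slice with the beta-mixture model
#'
#' Each (z, t) slice is independently pre-masked, fitted and thresholded:
#' voxels whose rescaled value is at least the slice threshold and that were
#' not pre-masked become ROI (1), all others background (0). Per-slice seeds
#' are derived deterministically from the global seed and the slice content,
#' so serial and parallel runs produce identical output and permuting
#' z-slices permutes the output identically. Slices where the whole slice is
#' constant are labeled entirely background; degenerate slices never abort
#' the stack.
#'
#' @param stack an \linkS4class{ImageStack4D}.
#' @param premaskPercentile background pre-mask percentile (default 99;
#'   astrocyte preset 98).
#' @param fallbackPercentile threshold percentile when only one component is
#'   detected (default 80; astrocyte preset 70).
#' @param minValues minimum retained values to attempt an EM fit.
#' @param maxIter,tol EM iteration cap and convergence tolerance.
#' @param seed global seed from which per-slice seeds are derived.
#' @param cores number of worker processes (forked via
#'   \code{parallel::mclapply}); results are identical to serial.
#' @return A list with \code{binary} (a \linkS4class{BinaryStack4D}) and
#'   \code{diagnostics} (a data.frame with one row per slice: z, t, number
#'   of retained values, fitted parameters, threshold, threshold source and
#'   convergence flag).
#' @export
binarizeStack <- function(stack, premaskPercentile = 99,
                          fallbackPercentile = 80, minValues = 50L,
                          maxIter = 200L, tol = 1e-6, seed = 1L, cores = 1L) {
  arr <- .asArray4(stack)
  d <- dim(arr)
  slices <- expand.grid(k = seq_len(d[3]), t = seq_len(d[4]))
  oneSlice <- function(i) {
    k <- slices$k[i]; t <- slices$t[i]
    slice <- arr[, , k, t]
    obs <- premaskSlice(slice, premaskPercentile)
    if (obs$degenerate) {
      return(list(bin = matrix(0L, d[1], d[2]),
                  diag = data.frame(z = k, t = t, nRetained = 0L,
                                    alpha0 = NA_real_, beta0 = NA_real_,
                                    alpha1 = NA_real_, beta1 = NA_real_,
                                    p0 = NA_real_, threshold = NA_real_,
                                    thresholdSource = "degenerate",
                                    nComponents = 0L, converged = FALSE)))
    }
    fit <- tryCatch(
      fitBetaMixEM(obs$values, seed = .sliceContentSeed(seed, slice),
                   maxIter = maxIter, tol = tol,
                   fallbackPercentile = fallbackPercentile,
                   minValues = minValues),
      error = function(e) .fallbackFit(obs$values, fallbackPercentile,
                                       length(obs$values)))
    bin <- matrix(0L, d[1], d[2])
    bin[obs$mask & obs$rescaled >= fit@threshold] <- 1L
    list(bin = bin,
         diag = data.frame(z = k, t = t, nRetained = fit@n,
                           alpha0 = fit@alpha0, beta0 = fit@beta0,
                           alpha1 = fit@alpha1, beta1 = fit@beta1,
                           p0 = fit@p0, threshold = fit@threshold,
                           thresholdSource = fit@thresholdSource,
                           nComponents = fit@nComponents,
                           converged = fit@converged))
  }
  res <- if (cores > 1L) {
    parallel::mclapply(seq_len(nrow(slices)), oneSlice, mc.cores = cores)
  } else {
    lapply(seq_len(nrow(slices)), oneSlice)
  }
  bin <- array(0L, dim = d)
  for (i in seq_len(nrow(slices)))
    bin[, , slices$k[i], slices$t[i]] <- res[[i]]$bin
  diagnostics <- do.call(rbind, lapply(res, `[[`, "diag"))
  rownames(diagnostics) <- NULL
  list(binary = BinaryStack4D(bin), diagnostics = diagnostics)
}
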
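# internal helpers shared across modules

# clamp to the open unit interval; the beta density is unbounded or zero at
# the endpoints, so fitted values must stay strictly inside (0, 1)
.clamp01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# empirical percentile (inverse ECDF, quantile type 1): always an observed
# value, so thresholds at a percentile correspond to actual intensities
.percentile <- function(x, p) {
  stats::quantile(x, p / 100, names = FALSE, type = 1)
}

# deterministic per-slice seed derived from (globalSeed, k, t); keeps serial
# and parallel slice processing identical. Result stays below 2^31.
.sliceSeed <- function(seed, k, t) {
  as.integer((as.double(seed %% 65521L) * 48271 +
              as.double(k) * 1299709 +
              as.double(t) * 15485863) %% 2147483629)
}

# per-slice seed derived from the global seed and the slice *content* (cheap
# hash), so that identical slices are fitted identically wherever they sit:
# permuting z-slices or timepoints permutes the binarized output exactly,
# and serial/parallel processing agree
.sliceContentSeed <- function(seed, slice) {
  v <- as.double(slice)
  h1 <- sum(v) %% 1048573
  h2 <- sum(v * (seq_along(v) %% 97)) %% 1048573
  as.integer((as.double(seed %% 65521L) * 48271 + h1 * 7919 + h2 * 104729) %%
               2147483629)
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# linear index of (x, y, z, t) coordinate rows in an array of dimensions d;
# double-valued to avoid integer overflow on large stacks
.linearIndex <- function(coords, d) {
  (as.double(coords[, 1]) - 1) +
    as.double(d[1]) * (as.double(coords[, 2]) - 1) +
    as.double(d[1]) * d[2] * (as.double(coords[, 3]) - 1) +
    as.double(d[1]) * d[2] * d[3] * (as.double(coords[, 4]) - 1) + 1
}

.asArray4 <- function(x) {
  if (methods::is(x, "BinaryStack4D") || methods::is(x, "ImageStack4D"))
    return(x@data)
  stopifnot(is.array(x), length(dim(x)) == 4L)
  x
}
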
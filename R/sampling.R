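#' Kennard-Stone calibration/prediction partitioning
#'
#' Deterministic max-min-distance design: the seed pair is the two samples at
#' maximal Euclidean distance in spectral space; each further calibration
#' sample is the one maximising its minimum distance to the already selected
#' set. Distance ties resolve to the lowest sample index, so the algorithm
#' needs no random seed.
#'
#' @param X sample-by-band matrix or a [SpectralDataset-class].
#' @param nTrain number of calibration samples, `2 <= nTrain < n`.
#' @return A `SplitResult` list with `trainIdx` (in selection order),
#'   `testIdx` (increasing) and `ratio`.
#' @examples
#' ks <- kennardStone(matrix(c(0, 1, 9, 10)), 2)
#' ks$trainIdx  # the maximal-distance pair
#' @export
kennardStone <- function(X, nTrain) {
  if (is(X, "SpectralDataset")) X <- intensities(X)
  X <- as.matrix(X)
  n <- nrow(X)
  stopIfNot(isCount(nTrain, 2L) && nTrain < n,
            "nTrain must satisfy 2 <= nTrain < n")
  D <- as.matrix(stats::dist(X))

  # seed pair: maximal distance; ties -> smallest (i, j) lexicographically
  best <- -Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (D[i, j] > best + 1e-12) {
        best <- D[i, j]; bi <- i; bj <- j
      }
    }
  }
  sel <- c(bi, bj)
  minDist <- pmin(D[, bi], D[, bj])
  while (length(sel) < nTrain) {
    minDist[sel] <- -Inf
    cand <- which(minDist > max(minDist) - 1e-12)[1] # tie -> lowest index
    sel <- c(sel, cand)
    minDist <- pmin(minDist, D[, cand])
  }
  structure(
    list(trainIdx = as.integer(sel),
         testIdx = setdiff(seq_len(n), sel),
         ratio = sprintf("%d:%d", nTrain, n - nTrain)),
    class = "SplitResult"
  )
}

#' Split a dataset with Kennard-Stone
#'
#' Convenience wrapper returning the calibration and prediction datasets. The
#' default `ratio = 2/3` reproduces the 60/30 partition of a 90-sample set.
#'
#' @param ds a [SpectralDataset-class].
#' @param ratio calibration fraction of the samples.
#' @return List with `train`, `test` (both `SpectralDataset`) and `split`.
#' @export
ksSplit <- function(ds, ratio = 2 / 3) {
  stopifnot(is(ds, "SpectralDataset"))
  nTrain <- round(nSamples(ds) * ratio)
  sp <- kennardStone(intensities(ds), nTrain)
  list(train = ds[sp$trainIdx, ], test = ds[sp$testIdx, ], split = sp)
}

#' Build cross-validation folds
#'
#' Random assignment of `n` samples to `k` disjoint folds whose sizes differ by
#' at most one.
#'
#' @param n number of samples.
#' @param k number of folds, `2 <= k <= n`.
#' @param seed RNG seed.
#' @return List of `k` integer index vectors.
#' @export
makeFolds <- function(n, k, seed = 1L) {
  stopIfNot(isCount(n, 2L), "n must be a count >= 2")
  stopIfNot(isCount(k, 2L) && k <= n, "k must satisfy 2 <= k <= n")
  withSeed(seed, {
    idx <- sample.int(n)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    unname(split(idx, rep(seq_len(k), times = sizes)))
  })
}
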
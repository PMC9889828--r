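#' Selector parameter set
#'
#' Parameters shared by the five model-population-analysis wavelength
#' selectors. `extras` carries the method-specific knobs the canonical
#' algorithms leave open; unset entries take the defaults below.
#'
#' * `bestFrac` (Boss/IVSO, default 0.1): fraction of sub-models retained for
#'   re-weighting.
#' * `maxIter` (Boss/IVSO/IVISSA/MASS, default 10): iteration cap of the
#'   space-shrinkage loop.
#' * `sampleFrac` (CARS, default 0.8): Monte-Carlo calibration fraction.
#' * `dropTol` (MASS, default 0): bands whose sampling weight falls to this
#'   value or below are removed from the candidate space.
#'
#' @param method `Boss`, `CARS`, `IVSO`, `IVISSA`, `MASS`, or `none`
#'   (keep all bands; useful as a baseline or as an identity cascade stage).
#' @param maxLv cap on PLS latent variables per sub-model.
#' @param kFolds cross-validation folds for RMSECV.
#' @param nSampling sub-models per iteration (bootstrap / Monte-Carlo / binary
#'   matrix rows).
#' @param seed RNG seed of the selector run.
#' @param extras named list of method-specific settings.
#' @return A validated `SelectorParams` list.
#' @export
selectorParams <- function(method = c("Boss", "CARS", "IVSO", "IVISSA", "MASS", "none"),
                           maxLv = 10L, kFolds = 5L, nSampling = 1000L,
                           seed = 1L, extras = list()) {
  method <- match.arg(method)
  stopIfNot(isCount(maxLv, 1L), "maxLv must be >= 1")
  stopIfNot(isCount(kFolds, 2L), "kFolds must be >= 2")
  stopIfNot(isCount(nSampling, 1L), "nSampling must be >= 1")
  defaults <- list(bestFrac = 0.1, maxIter = 10L, sampleFrac = 0.8, dropTol = 0)
  extras <- utils::modifyList(defaults, extras)
  stopIfNot(extras$bestFrac > 0 && extras$bestFrac <= 1, "bestFrac in (0, 1]")
  stopIfNot(extras$sampleFrac > 0 && extras$sampleFrac <= 1, "sampleFrac in (0, 1]")
  structure(list(method = method, maxLv = as.integer(maxLv),
                 kFolds = as.integer(kFolds), nSampling = as.integer(nSampling),
                 seed = as.integer(seed), extras = extras),
            class = "SelectorParams")
}

# Score one sub-model: RMSECV over the lv grid, and the |coefficient| profile
# of the full-calibration fit at the selected lv (used for re-weighting).
scoreSubmodel <- function(X, y, bands, maxLv, folds, wantCoef = TRUE) {
  cv <- plsRMSECV(X, y, bands, maxLv, folds)
  coefAbs <- NULL
  if (wantCoef) {
    fit <- plsCoefficients(X[, bands, drop = FALSE], y, cv$bestLv)
    coefAbs <- abs(fit$coef)
  }
  list(rmsecv = cv$rmsecv, bestLv = cv$bestLv, coefAbs = coefAbs)
}

finishSelection <- function(method, sets, trace, weights, params) {
  best <- which.min(trace)
  SelectionResult(method = method, selected = sets[[best]],
                  rmsecvTrace = trace, bestIteration = best,
                  weightsFinal = weights, params = params)
}

#' Bootstrapping soft shrinkage (Boss) wavelength selection
#'
#' Iterative soft-shrinkage loop: starting from equal band weights, each
#' iteration draws `nSampling` variable sets by weighted bootstrap sampling
#' (sample `|candidate|` variables with replacement, inclusion probability
#' proportional to weight, de-duplicated), scores each sub-model by PLS
#' RMSECV, retains the best `bestFrac` fraction, and sets each band's new
#' weight to the summed normalised absolute PLS regression coefficients over
#' the retained sub-models. Weights decay gradually (soft shrinkage); a band
#' leaves the candidate space only when its weight reaches zero. The selected
#' set is the sub-model support at the global RMSECV minimum.
#'
#' @param X calibration sample-by-band matrix.
#' @param y calibration SSC vector (Brix).
#' @param params a [selectorParams()] with `method = "Boss"`.
#' @return A [SelectionResult-class].
#' @export
runBoss <- function(X, y, params) {
  stopifnot(inherits(params, "SelectorParams"), params$method == "Boss")
  X <- as.matrix(X)
  p <- ncol(X)
  folds <- makeFolds(nrow(X), params$kFolds, deriveSeed(params$seed, 0L))
  if (p == 1L) {
    sc <- scoreSubmodel(X, y, 1L, params$maxLv, folds, wantCoef = FALSE)
    return(finishSelection("Boss", list(1L), sc$rmsecv, 1, params))
  }
  weights <- rep(1 / p, p)
  trace <- numeric(0)
  sets <- list()
  withSeed(deriveSeed(params$seed, 1L), {
    for (iter in seq_len(params$extras$maxIter)) {
      cand <- which(weights > 0)
      if (length(cand) <= 1L) break
      subs <- lapply(seq_len(params$nSampling), function(s) {
        sort(unique(sample(cand, length(cand), replace = TRUE,
                           prob = weights[cand])))
      })
      scores <- lapply(subs, function(b)
        scoreSubmodel(X, y, b, params$maxLv, folds))
      rmse <- vapply(scores, `[[`, 0, "rmsecv")
      nBest <- max(1L, round(params$extras$bestFrac * params$nSampling))
      keep <- order(rmse)[seq_len(nBest)]
      newW <- numeric(p)
      for (ki in keep) {
        ca <- scores[[ki]]$coefAbs
        tot <- sum(ca)
        if (tot > 0) newW[subs[[ki]]] <- newW[subs[[ki]]] + ca / tot
      }
      trace <- c(trace, min(rmse))
      sets[[length(sets) + 1L]] <- subs[[which.min(rmse)]]
      if (all(newW == 0)) break
      supportStable <- identical(which(newW > 0), cand)
      weights <- newW
      if (supportStable && iter > 1L) break
    }
  })
  stopIfNot(length(trace) > 0L, "Boss: no sub-model could be scored")
  finishSelection("Boss", sets, trace, weights, params)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' For run `i = 1..nSampling`: draw a Monte-Carlo calibration subset
#' (`sampleFrac` of the samples), fit PLS on the current band set, then apply
#' the exponentially decreasing function (EDF) retain-ratio
#' `r_i = a * exp(-k * i)` with `a, k` fixed by `r_1 = 1` and
#' `r_N = 2/p`, and keep `ceil(r_i * p)` bands drawn with probability
#' proportional to the normalised absolute regression coefficients (adaptive
#' reweighted sampling; de-duplicated). Each run records the k-fold RMSECV of
#' its retained set; the selection is the retained set of the best run.
#'
#' @inheritParams runBoss
#' @param params a [selectorParams()] with `method = "CARS"`.
#' @return A [SelectionResult-class].
#' @export
runCars <- function(X, y, params) {
  stopifnot(inherits(params, "SelectorParams"), params$method == "CARS")
  X <- as.matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  N <- params$nSampling
  folds <- makeFolds(n, params$kFolds, deriveSeed(params$seed, 0L))
  if (p == 1L) {
    sc <- scoreSubmodel(X, y, 1L, params$maxLv, folds, wantCoef = FALSE)
    return(finishSelection("CARS", list(1L), sc$rmsecv, 1, params))
  }
  ratio <- carsRetainRatio(seq_len(N), N, p)
  trace <- numeric(0)
  sets <- list()
  weights <- rep(1, p)
  withSeed(deriveSeed(params$seed, 1L), {
    current <- seq_len(p)
    for (i in seq_len(N)) {
      prev <- current
      rows <- sample.int(n, max(2L, round(params$extras$sampleFrac * n)))
      lv <- max(1L, min(params$maxLv, length(prev), length(rows) - 1L))
      fit <- plsCoefficients(X[rows, prev, drop = FALSE], y[rows], lv)
      w <- abs(fit$coef)
      if (sum(w) == 0) w <- rep(1, length(prev))
      keepN <- ceiling(ratio[i] * p)
      current <- if (keepN < length(prev)) {
        sort(unique(sample(prev, keepN, replace = TRUE, prob = w)))
      } else {
        prev
      }
      if (length(current) == 0L) break
      weights <- numeric(p)
      weights[current] <- w[match(current, prev)]
      sc <- plsRMSECV(X, y, current, params$maxLv, folds)
      trace <- c(trace, sc$rmsecv)
      sets[[length(sets) + 1L]] <- current
      if (length(current) <= 2L) break
    }
  })
  stopIfNot(length(trace) > 0L, "CARS: no run completed")
  finishSelection("CARS", sets, trace, pmax(weights, 0), params)
}

# EDF retain ratio r_i = a * exp(-k * i), a and k fixed by the boundary
# conditions r_1 = 1 (all p bands kept at the first run) and r_N = 2/p
# (two bands at the last run).
carsRetainRatio <- function(i, N, p) {
  if (N == 1L) return(rep(1, length(i)))
  k <- log(p / 2) / (N - 1)
  a <- exp(k)
  pmin(1, a * exp(-k * i))
}

# Draw one iteration's binary inclusion matrix. First iteration: each band is
# included in exactly half the rows (uniformly placed); later iterations:
# Bernoulli inclusion with probability proportional to weight, scaled so the
# best band keeps the initial 0.5 inclusion rate. Empty rows get the current
# top-weight band so every sub-model is fittable.
binaryInclusionMatrix <- function(nRows, cand, weights, first) {
  M <- matrix(FALSE, nRows, length(cand))
  if (first) {
    half <- max(1L, nRows %/% 2L)
    for (j in seq_along(cand)) M[sample.int(nRows, half), j] <- TRUE
  } else {
    pj <- 0.5 * weights[cand] / max(weights[cand])
    M <- matrix(stats::runif(nRows * length(cand)) <
                  matrix(pj, nRows, length(cand), byrow = TRUE),
                nRows, length(cand))
  }
  empty <- rowSums(M) == 0L
  if (any(empty)) M[empty, which.max(weights[cand])] <- TRUE
  M
}

# Shared engine of the binary-matrix-sampling selectors (IVSO; also the global
# step of IVISSA). Returns the new weights plus this iteration's best
# sub-model.
wbmsIteration <- function(X, y, cand, weights, params, folds, first) {
  M <- binaryInclusionMatrix(params$nSampling, cand, weights, first)
  subs <- apply(M, 1L, function(r) cand[r], simplify = FALSE)
  scores <- lapply(subs, function(b) scoreSubmodel(X, y, b, params$maxLv, folds))
  rmse <- vapply(scores, `[[`, 0, "rmsecv")
  nBest <- max(1L, round(params$extras$bestFrac * params$nSampling))
  keep <- order(rmse)[seq_len(nBest)]
  newW <- numeric(ncol(X))
  for (ki in keep) {
    ca <- scores[[ki]]$coefAbs
    tot <- sum(ca)
    if (tot > 0) newW[subs[[ki]]] <- newW[subs[[ki]]] + ca / tot
  }
  list(weights = newW, bestSet = subs[[which.min(rmse)]], bestRmse = min(rmse))
}

#' Iteratively variable subset optimisation (IVSO)
#'
#' Weighted binary-matrix sampling: iteration 1 includes each band in half of
#' the `nSampling` binary rows uniformly; each row is a PLS sub-model scored by
#' RMSECV; band weights are the summed normalised absolute coefficients over
#' the best `bestFrac` sub-models; subsequent iterations include bands with
#' probability proportional to weight and drop zero-weight bands. The selected
#' set is the globally best sub-model.
#'
#' @inheritParams runBoss
#' @param params a [selectorParams()] with `method = "IVSO"`.
#' @return A [SelectionResult-class].
#' @export
runIvso <- function(X, y, params) {
  stopifnot(inherits(params, "SelectorParams"), params$method == "IVSO")
  X <- as.matrix(X)
  p <- ncol(X)
  folds <- makeFolds(nrow(X), params$kFolds, deriveSeed(params$seed, 0L))
  if (p == 1L) {
    sc <- scoreSubmodel(X, y, 1L, params$maxLv, folds, wantCoef = FALSE)
    return(finishSelection("IVSO", list(1L), sc$rmsecv, 1, params))
  }
  weights <- rep(1, p)
  trace <- numeric(0)
  sets <- list()
  withSeed(deriveSeed(params$seed, 1L), {
    cand <- seq_len(p)
    for (iter in seq_len(params$extras$maxIter)) {
      it <- wbmsIteration(X, y, cand, weights, params, folds, iter == 1L)
      trace <- c(trace, it$bestRmse)
      sets[[length(sets) + 1L]] <- it$bestSet
      newCand <- which(it$weights > 0)
      if (length(newCand) <= 1L) { weights <- it$weights; break }
      stable <- identical(newCand, cand)
      weights <- it$weights
      cand <- newCand
      if (stable && iter > 1L) break
    }
  })
  stopIfNot(length(trace) > 0L, "IVSO: no sub-model could be scored")
  finishSelection("IVSO", sets, trace, weights, params)
}

# Contiguous runs of a sorted index set -> list of c(from, to).
contiguousIntervals <- function(idx) {
  idx <- sort(idx)
  breaks <- which(diff(idx) > 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  Map(function(s, e) c(idx[s], idx[e]), starts, ends)
}

#' Interval variable iterative space shrinkage approach (IVISSA)
#'
#' Alternates a global step (the weighted binary-matrix sampling machinery of
#' [runIvso()]) with a local step that, for each contiguous interval of the
#' current selection, tries widening or narrowing by one band on each side and
#' keeps the best variant by RMSECV. Iterates until the cross-validated error
#' stops improving or `maxIter` is reached; the selection is the union of the
#' final intervals at the globally best iteration.
#'
#' @inheritParams runBoss
#' @param params a [selectorParams()] with `method = "IVISSA"`.
#' @return A [SelectionResult-class].
#' @export
runIvissa <- function(X, y, params) {
  stopifnot(inherits(params, "SelectorParams"), params$method == "IVISSA")
  X <- as.matrix(X)
  p <- ncol(X)
  folds <- makeFolds(nrow(X), params$kFolds, deriveSeed(params$seed, 0L))
  if (p == 1L) {
    sc <- scoreSubmodel(X, y, 1L, params$maxLv, folds, wantCoef = FALSE)
    return(finishSelection("IVISSA", list(1L), sc$rmsecv, 1, params))
  }
  weights <- rep(1, p)
  trace <- numeric(0)
  sets <- list()
  withSeed(deriveSeed(params$seed, 1L), {
    cand <- seq_len(p)
    for (iter in seq_len(params$extras$maxIter)) {
      it <- wbmsIteration(X, y, cand, weights, params, folds, iter == 1L)
      sel <- it$bestSet
      best <- plsRMSECV(X, y, sel, params$maxLv, folds)$rmsecv
      # local step: adjust each contiguous interval one band at a time
      sel <- localIntervalStep(X, y, sel, params, folds, best)
      best <- plsRMSECV(X, y, sel$bands, params$maxLv, folds)$rmsecv
      trace <- c(trace, best)
      sets[[length(sets) + 1L]] <- sel$bands
      newCand <- which(it$weights > 0)
      if (length(newCand) <= 1L) { weights <- it$weights; break }
      weights <- it$weights
      if (iter > 1L && trace[iter] >= trace[iter - 1L] - 1e-10) break
      cand <- newCand
    }
  })
  stopIfNot(length(trace) > 0L, "IVISSA: no sub-model could be scored")
  finishSelection("IVISSA", sets, trace, weights, params)
}

# One pass of interval widening/narrowing. For each contiguous interval of
# `bands`, evaluate moving each boundary in/out by one band and keep the best
# variant if it improves the RMSECV; an already optimal interval is unchanged.
localIntervalStep <- function(X, y, bands, params, folds, currentRmse) {
  p <- ncol(X)
  bands <- sort(bands)
  for (iv in contiguousIntervals(bands)) {
    variants <- list()
    if (iv[1] > 1L && !(iv[1] - 1L) %in% bands)
      variants <- c(variants, list(c(bands, iv[1] - 1L)))
    if (iv[2] < p && !(iv[2] + 1L) %in% bands)
      variants <- c(variants, list(c(bands, iv[2] + 1L)))
    if (iv[2] > iv[1])
      variants <- c(variants, list(setdiff(bands, iv[1])),
                    list(setdiff(bands, iv[2])))
    for (v in variants) {
      v <- sort(unique(v))
      if (length(v) == 0L) next
      r <- plsRMSECV(X, y, v, params$maxLv, folds)$rmsecv
      if (r < currentRmse - 1e-10) {
        bands <- v
        currentRmse <- r
      }
    }
  }
  list(bands = sort(bands), rmsecv = currentRmse)
}

#' Model adaptive space shrinkage (MASS)
#'
#' Per iteration: draw `nSampling` sub-models by weighted binary-matrix
#' sampling (inclusion probability = the band's current weight, initially 0.5),
#' score them by PLS RMSECV, split at the median score, and set each band's new
#' weight to its inclusion frequency among the better half. Bands whose weight
#' falls to `dropTol` (default 0) or below leave the candidate space. The
#' selection is the globally best sub-model.
#'
#' @inheritParams runBoss
#' @param params a [selectorParams()] with `method = "MASS"`.
#' @return A [SelectionResult-class].
#' @export
runMass <- function(X, y, params) {
  stopifnot(inherits(params, "SelectorParams"), params$method == "MASS")
  X <- as.matrix(X)
  p <- ncol(X)
  folds <- makeFolds(nrow(X), params$kFolds, deriveSeed(params$seed, 0L))
  if (p == 1L) {
    sc <- scoreSubmodel(X, y, 1L, params$maxLv, folds, wantCoef = FALSE)
    return(finishSelection("MASS", list(1L), sc$rmsecv, 1, params))
  }
  weights <- rep(0.5, p)
  trace <- numeric(0)
  sets <- list()
  withSeed(deriveSeed(params$seed, 1L), {
    cand <- seq_len(p)
    stableRuns <- 0L
    for (iter in seq_len(params$extras$maxIter)) {
      M <- matrix(stats::runif(params$nSampling * length(cand)) <
                    matrix(weights[cand], params$nSampling, length(cand),
                           byrow = TRUE),
                  params$nSampling, length(cand))
      empty <- rowSums(M) == 0L
      if (any(empty)) M[empty, which.max(weights[cand])] <- TRUE
      subs <- apply(M, 1L, function(r) cand[r], simplify = FALSE)
      rmse <- vapply(subs, function(b)
        plsRMSECV(X, y, b, params$maxLv, folds)$rmsecv, 0)
      better <- which(rmse <= stats::median(rmse))
      freq <- colMeans(M[better, , drop = FALSE])
      newW <- numeric(p)
      newW[cand] <- freq
      trace <- c(trace, min(rmse))
      sets[[length(sets) + 1L]] <- subs[[which.min(rmse)]]
      newCand <- which(newW > params$extras$dropTol)
      if (length(newCand) <= 1L) { weights <- newW; break }
      stableRuns <- if (identical(newCand, cand)) stableRuns + 1L else 0L
      weights <- newW
      cand <- newCand
      # the space is declared stable after three consecutive iterations with
      # no removal (a single quiet iteration is common while weights evolve)
      if (stableRuns >= 3L) break
    }
  })
  stopIfNot(length(trace) > 0L, "MASS: no sub-model could be scored")
  finishSelection("MASS", sets, trace, weights, params)
}

#' Run a selector by name
#'
#' Dispatch wrapper over [runBoss()], [runCars()], [runIvso()], [runIvissa()]
#' and [runMass()]; `method = "none"` returns all bands with a single RMSECV
#' evaluation (the no-selection baseline).
#'
#' @inheritParams runBoss
#' @param params a [selectorParams()].
#' @return A [SelectionResult-class].
#' @export
runSelector <- function(X, y, params) {
  stopifnot(inherits(params, "SelectorParams"))
  if (params$method == "none") {
    X <- as.matrix(X)
    folds <- makeFolds(nrow(X), params$kFolds, deriveSeed(params$seed, 0L))
    sc <- plsRMSECV(X, y, NULL, params$maxLv, folds)
    return(SelectionResult("none", seq_len(ncol(X)), sc$rmsecv, 1L,
                           rep(1, ncol(X)), params))
  }
  switch(params$method,
    Boss = runBoss(X, y, params),
    CARS = runCars(X, y, params),
    IVSO = runIvso(X, y, params),
    IVISSA = runIvissa(X, y, params),
    MASS = runMass(X, y, params)
  )
}

#' Cascade two selectors (secondary feature extraction)
#'
#' Runs `first` on all bands, then `then` restricted to the first stage's
#' selected bands; returned indices are in original-band coordinates, so the
#' result is always a subset of the first stage's selection. If the first
#' stage returns fewer than 2 bands the second stage is skipped and the
#' first-stage result is returned with a `cascadeSkipped` flag in its params.
#'
#' @inheritParams runBoss
#' @param first,then [selectorParams()] for the two stages.
#' @return A [SelectionResult-class] with method `"<first>-<then>"`.
#' @export
runCascade <- function(X, y, first, then) {
  stopifnot(inherits(first, "SelectorParams"), inherits(then, "SelectorParams"))
  X <- as.matrix(X)
  r1 <- runSelector(X, y, first)
  if (length(r1@selected) < 2L) {
    warning("first stage selected < 2 bands; second stage skipped")
    r1@params$cascadeSkipped <- TRUE
    return(r1)
  }
  r2 <- runSelector(X[, r1@selected, drop = FALSE], y, then)
  mapped <- r1@selected[r2@selected]
  wFull <- numeric(ncol(X))
  wFull[r1@selected] <- r2@weightsFinal
  SelectionResult(
    method = paste(first$method, then$method, sep = "-"),
    selected = mapped, rmsecvTrace = r2@rmsecvTrace,
    bestIteration = r2@bestIteration, weightsFinal = wFull,
    params = list(first = first, then = then)
  )
}

#' Summarise a selection
#'
#' @param result a [SelectionResult-class].
#' @param totalBands total candidate bands of the grid.
#' @return List with `nSelected` and `percent` (share of the grid, percent to
#'   one decimal; e.g. 19 of 229 bands is 8.3).
#' @export
selectionSummary <- function(result, totalBands) {
  n <- if (is(result, "SelectionResult")) length(result@selected) else as.integer(result)
  stopIfNot(totalBands >= n, "totalBands must be >= the selection size")
  list(nSelected = n, percent = round(100 * n / totalBands, 1))
}

#' Serialise a selection result to JSON
#'
#' Writes method, parameters, selected indices (0-based, for interoperability
#' with array-indexed tooling), selected wavelengths and the RMSECV trace.
#'
#' @param result a [SelectionResult-class].
#' @param wavelengths the band grid the indices refer to.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSelection <- function(result, wavelengths, path) {
  stopifnot(is(result, "SelectionResult"))
  obj <- list(
    method = result@method,
    params = result@params[setdiff(names(result@params), "extras")],
    selected = result@selected - 1L,
    selected_wavelengths_nm = wavelengths[result@selected],
    rmsecv_trace = result@rmsecvTrace,
    best_iteration = result@bestIteration
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
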
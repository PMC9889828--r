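#' Cross-validated RMSE of a PLS sub-model
#'
#' The scoring engine shared by every wavelength selector: fits PLS1 (NIPALS)
#' per fold for 1..`maxLv` latent variables on the requested band subset and
#' returns the minimal cross-validated RMSE over the latent-variable grid
#' together with the argmin (ties resolve to the smaller count). The fold
#' assignment is passed in, so all sub-models of one selector run are scored on
#' identical folds.
#'
#' The latent-variable grid is capped at `min(maxLv, |subset|,
#' min_fold(nTrain) - 1)`; a fold that cannot support a component count simply
#' caps the grid rather than erroring.
#'
#' @param X calibration sample-by-band matrix.
#' @param y calibration SSC vector (Brix).
#' @param subset band indices to use; `NULL` = all bands.
#' @param maxLv maximum number of latent variables.
#' @param folds list of test-index vectors, e.g. from [makeFolds()].
#' @return List with `rmsecv` (Brix), `bestLv`, and `perLv` (RMSECV for
#'   1..cap latent variables).
#' @export
plsRMSECV <- function(X, y, subset = NULL, maxLv, folds) {
  X <- as.matrix(X)
  if (!is.null(subset)) {
    stopIfNot(length(subset) > 0L, "subset must be non-empty")
    X <- X[, subset, drop = FALSE]
  }
  stopIfNot(isCount(maxLv, 1L), "maxLv must be a count >= 1")
  per <- .cppPlsCvRmse(X, as.numeric(y), lapply(folds, as.integer),
                       as.integer(maxLv))
  # smallest lv within numerical tolerance of the minimum, so floating-point
  # near-ties on noiseless data still resolve to the simpler model
  best <- which(per <= min(per) + max(1e-12, 1e-8 * min(per)))[1]
  list(rmsecv = per[best], bestLv = as.integer(best), perLv = as.numeric(per))
}

#' Choose the number of PLSR latent variables by cross-validation
#'
#' @inheritParams plsRMSECV
#' @return The latent-variable count minimising the cross-validated RMSE
#'   (smallest count on ties).
#' @export
selectLvs <- function(X, y, maxLv, folds) {
  plsRMSECV(X, y, NULL, maxLv, folds)$bestLv
}

# Full-data PLS1 fit; returns coefficients (original scale) and intercept for
# exactly `lv` components.
plsCoefficients <- function(X, y, lv) {
  fit <- .cppPlsFit(as.matrix(X), as.numeric(y), as.integer(lv))
  a <- min(lv, ncol(fit$coefs))
  list(coef = as.numeric(fit$coefs[, a]), intercept = fit$intercepts[a])
}
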
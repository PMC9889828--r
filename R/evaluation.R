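#' Coefficient of determination
#'
#' `1 - sum((y - f)^2) / sum((y - mean(y))^2)`, computed against the mean of
#' the set being evaluated (so the prediction-set R2 uses the prediction-set
#' mean).
#'
#' @param y reference values.
#' @param f predicted values.
#' @return R2; 1 for a perfect fit, 0 for the mean predictor, negative when
#'   worse than the mean.
#' @export
rSquared <- function(y, f) {
  stopIfNot(length(y) == length(f) && length(y) >= 2L,
            "y and f must have equal length >= 2")
  stopIfNot(stats::var(y) > 0, "y has zero variance; R2 undefined")
  1 - sum((y - f)^2) / sum((y - mean(y))^2)
}

#' Root mean square error
#'
#' @param y reference values.
#' @param f predicted values.
#' @return `sqrt(mean((f - y)^2))`, in Brix for SSC models.
#' @export
rmse <- function(y, f) {
  stopIfNot(length(y) == length(f) && length(y) >= 1L,
            "y and f must have equal length >= 1")
  sqrt(mean((f - y)^2))
}

#' Residual prediction deviation
#'
#' Standard deviation of the prediction-set reference values divided by the
#' RMSEP. The sample (n-1) standard deviation is the default; a population
#' toggle is provided since either convention appears in practice.
#'
#' @param yTest prediction-set reference values (length >= 2).
#' @param rmsep root mean square error of prediction, `> 0`.
#' @param unbiased use the (n-1)-denominator standard deviation.
#' @return RPD (dimensionless).
#' @export
rpd <- function(yTest, rmsep, unbiased = TRUE) {
  stopIfNot(length(yTest) >= 2L, "need at least 2 prediction-set values")
  stopIfNot(is.numeric(rmsep) && rmsep > 0,
            "rmsep must be > 0 (a perfect fit has no finite RPD)")
  s <- stats::sd(yTest)
  if (!unbiased) s <- s * sqrt((length(yTest) - 1) / length(yTest))
  s / rmsep
}

#' Grade a model by its RPD
#'
#' `RPD < 1.4` is poor, `1.4 <= RPD < 2` average, `RPD >= 2` good.
#'
#' @param x RPD value(s).
#' @return Character vector of grades.
#' @export
gradeRPD <- function(x) {
  ifelse(x >= 2, "good", ifelse(x >= 1.4, "average", "poor"))
}

#' Evaluate a fitted model on calibration and prediction sets
#'
#' Computes R2c/RMSEC on the calibration set and R2p/RMSEP/RPD on the
#' prediction set, restricted to the selected bands, and assembles one report
#' row with provenance. The prediction-set targets are touched only after the
#' predictions are made.
#'
#' @param fit a [FitResult-class] trained on the selected bands of `train`.
#' @param train,test calibration and prediction [SpectralDataset-class]s.
#' @param selection a [SelectionResult-class], or `NULL` for all bands.
#' @param pipeline optional pipeline label for the report row.
#' @return One-row `data.frame`: `pipeline`, `model`, `nFeatures`, `R2c`,
#'   `RMSEC`, `R2p`, `RMSEP`, `RPD`, `grade`.
#' @export
evaluateModel <- function(fit, train, test, selection = NULL, pipeline = NA_character_) {
  stopifnot(is(fit, "FitResult"), is(train, "SpectralDataset"),
            is(test, "SpectralDataset"))
  sel <- if (is.null(selection)) seq_len(nBands(train)) else selectedBands(selection)
  stopIfNot(max(sel) <= nBands(train) && max(sel) <= nBands(test),
            "selection indices out of range for the datasets")
  fitBands <- switch(fit@modelType,
    PLSR = length(fit@learned$coef),
    ELM = ncol(fit@learned$W),
    LSSVM = ncol(fit@learned$Xs)
  )
  stopIfNot(fitBands == length(sel),
            "fit band count does not match the selection")
  predTrain <- predict(fit, intensities(train)[, sel, drop = FALSE])
  predTest <- predict(fit, intensities(test)[, sel, drop = FALSE])
  yTr <- ssc(train)
  yTe <- ssc(test)
  rmsep <- rmse(yTe, predTest)
  rpdVal <- if (rmsep > 0) rpd(yTe, rmsep) else Inf
  data.frame(
    pipeline = pipeline,
    model = fit@modelType,
    nFeatures = length(sel),
    R2c = rSquared(yTr, predTrain),
    RMSEC = rmse(yTr, predTrain),
    R2p = rSquared(yTe, predTest),
    RMSEP = rmsep,
    RPD = rpdVal,
    grade = gradeRPD(rpdVal),
    stringsAsFactors = FALSE
  )
}
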
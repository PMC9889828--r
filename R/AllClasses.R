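#' @import methods
NULL

#' SpectralDataset: a spectral table with reference SSC values
#'
#' The container every pipeline stage consumes and produces: a strictly
#' increasing wavelength grid (nm), an `n_samples x n_bands` intensity matrix
#' (reflectance for HSI, emission intensity for FSI, arbitrary units), the
#' reference soluble-solid content in degrees Brix, a modality tag and free-text
#' provenance.
#'
#' @slot wavelengths numeric, strictly increasing, nm.
#' @slot X numeric matrix, samples in rows, bands in columns.
#' @slot y numeric, reference SSC per sample (degrees Brix).
#' @slot modality `"HSI"` (reflectance) or `"FSI"` (fluorescence emission).
#' @slot sampleIds character, one id per sample.
#' @slot provenance character scalar describing how the data arose.
#'
#' @export
setClass("SpectralDataset",
  slots = c(
    wavelengths = "numeric",
    X = "matrix",
    y = "numeric",
    modality = "character",
    sampleIds = "character",
    provenance = "character"
  )
)

setValidity("SpectralDataset", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "nrow(X) must equal length(y)")
  if (nrow(object@X) != length(object@sampleIds))
    msg <- c(msg, "nrow(X) must equal length(sampleIds)")
  if (ncol(object@X) != length(object@wavelengths))
    msg <- c(msg, "ncol(X) must equal length(wavelengths)")
  if (length(object@wavelengths) >= 2 && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!all(is.finite(object@X)))
    msg <- c(msg, "X contains non-finite entries")
  if (!all(is.finite(object@y)))
    msg <- c(msg, "y contains non-finite entries")
  if (length(object@modality) != 1L || !object@modality %in% c("HSI", "FSI"))
    msg <- c(msg, "modality must be \"HSI\" or \"FSI\"")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sampleIds must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralDataset
#'
#' @param wavelengths strictly increasing wavelength grid in nm.
#' @param X sample-by-band intensity matrix.
#' @param y reference SSC vector (degrees Brix).
#' @param modality `"HSI"` or `"FSI"`.
#' @param sampleIds sample identifiers; defaults to `s1, s2, ...`.
#' @param provenance free-text origin of the data.
#' @return A validated [SpectralDataset-class] object.
#' @export
SpectralDataset <- function(wavelengths, X, y, modality,
                            sampleIds = paste0("s", seq_len(nrow(X))),
                            provenance = "unspecified") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  new("SpectralDataset",
    wavelengths = as.numeric(wavelengths), X = X, y = as.numeric(y),
    modality = modality, sampleIds = as.character(sampleIds),
    provenance = provenance
  )
}

setMethod("show", "SpectralDataset", function(object) {
  cat(sprintf(
    "SpectralDataset (%s): %d samples x %d bands, %.2f-%.2f nm\n",
    object@modality, nrow(object@X), ncol(object@X),
    min(object@wavelengths), max(object@wavelengths)
  ))
  cat(sprintf(
    "  SSC: %.2f-%.2f Brix (mean %.2f, sd %.2f)\n",
    min(object@y), max(object@y), mean(object@y), stats::sd(object@y)
  ))
  cat("  provenance:", object@provenance, "\n")
})

#' SelectionResult: output of a wavelength selector
#'
#' @slot method selector name (`Boss`, `CARS`, `IVSO`, `IVISSA`, `MASS`, a
#'   cascade such as `MASS-Boss`, or `none`).
#' @slot selected strictly increasing 1-based band indices.
#' @slot rmsecvTrace RMSECV of the best sub-model per iteration/run (Brix).
#' @slot bestIteration index into `rmsecvTrace` attaining its minimum.
#' @slot weightsFinal non-negative final sampling weight per candidate band.
#' @slot params the `selectorParams()` list that produced the result.
#'
#' @export
setClass("SelectionResult",
  slots = c(
    method = "character",
    selected = "integer",
    rmsecvTrace = "numeric",
    bestIteration = "integer",
    weightsFinal = "numeric",
    params = "list"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (length(object@selected) == 0L)
    msg <- c(msg, "selected must be non-empty")
  if (anyDuplicated(object@selected))
    msg <- c(msg, "selected indices must be unique")
  if (is.unsorted(object@selected, strictly = TRUE))
    msg <- c(msg, "selected indices must be strictly increasing")
  if (any(object@selected < 1L))
    msg <- c(msg, "selected indices must be >= 1")
  if (length(object@rmsecvTrace) == 0L)
    msg <- c(msg, "rmsecvTrace must be non-empty")
  if (length(object@bestIteration) != 1L ||
      object@bestIteration < 1L ||
      object@bestIteration > length(object@rmsecvTrace))
    msg <- c(msg, "bestIteration out of range")
  else if (abs(object@rmsecvTrace[object@bestIteration] -
               min(object@rmsecvTrace)) > 1e-12)
    msg <- c(msg, "rmsecvTrace[bestIteration] must equal min(rmsecvTrace)")
  if (any(object@weightsFinal < 0))
    msg <- c(msg, "weightsFinal must be non-negative")
  if (length(msg)) msg else TRUE
})

SelectionResult <- function(method, selected, rmsecvTrace, bestIteration,
                            weightsFinal, params) {
  new("SelectionResult",
    method = method, selected = as.integer(sort(unique(selected))),
    rmsecvTrace = as.numeric(rmsecvTrace),
    bestIteration = as.integer(bestIteration),
    weightsFinal = as.numeric(weightsFinal),
    params = unclass(params)
  )
}

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult [%s]: %d bands, best RMSECV %.4f at iteration %d/%d\n",
    object@method, length(object@selected),
    min(object@rmsecvTrace), object@bestIteration, length(object@rmsecvTrace)
  ))
})

#' FitResult: a trained regressor
#'
#' Holds everything needed to predict: the model family, its hyperparameters,
#' the learned coefficient containers, and the training-set summary
#' (`R2c`, `RMSEC`).
#'
#' @slot modelType `"PLSR"`, `"ELM"` or `"LSSVM"`.
#' @slot hyperparams named list (lvs; nHidden + seed; gamma + sigma2).
#' @slot learned named list of learned coefficients and scaling statistics.
#' @slot trainSummary named numeric `c(R2c = ..., RMSEC = ...)`.
#'
#' @export
setClass("FitResult",
  slots = c(
    modelType = "character",
    hyperparams = "list",
    learned = "list",
    trainSummary = "numeric"
  )
)

setValidity("FitResult", function(object) {
  msg <- character()
  if (!object@modelType %in% c("PLSR", "ELM", "LSSVM"))
    msg <- c(msg, "modelType must be PLSR, ELM or LSSVM")
  if (!all(c("R2c", "RMSEC") %in% names(object@trainSummary)))
    msg <- c(msg, "trainSummary must contain R2c and RMSEC")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FitResult", function(object) {
  hp <- paste(names(object@hyperparams),
              vapply(object@hyperparams, function(v) paste(format(v), collapse = ","), ""),
              sep = "=", collapse = ", ")
  cat(sprintf(
    "FitResult [%s] (%s): R2c = %.4f, RMSEC = %.4f\n",
    object@modelType, hp,
    object@trainSummary[["R2c"]], object@trainSummary[["RMSEC"]]
  ))
})
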
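#' Accessor generics for spectral objects
#'
#' `wavelengths()`, `intensities()`, `ssc()`, `modality()`, `sampleIds()`,
#' `nSamples()` and `nBands()` read the corresponding parts of a
#' [SpectralDataset-class]; `selectedBands()` and `rmsecvTrace()` read a
#' [SelectionResult-class].
#'
#' @param object a `SpectralDataset` or `SelectionResult`.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("ssc", function(object) standardGeneric("ssc"))
#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nBands", function(object) standardGeneric("nBands"))
#' @rdname accessors
#' @export
setGeneric("selectedBands", function(object) standardGeneric("selectedBands"))
#' @rdname accessors
#' @export
setGeneric("rmsecvTrace", function(object) standardGeneric("rmsecvTrace"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralDataset", function(object) object@wavelengths)
#' @rdname accessors
#' @export
setMethod("intensities", "SpectralDataset", function(object) object@X)
#' @rdname accessors
#' @export
setMethod("ssc", "SpectralDataset", function(object) object@y)
#' @rdname accessors
#' @export
setMethod("modality", "SpectralDataset", function(object) object@modality)
#' @rdname accessors
#' @export
setMethod("sampleIds", "SpectralDataset", function(object) object@sampleIds)
#' @rdname accessors
#' @export
setMethod("nSamples", "SpectralDataset", function(object) nrow(object@X))
#' @rdname accessors
#' @export
setMethod("nBands", "SpectralDataset", function(object) ncol(object@X))
#' @rdname accessors
#' @export
setMethod("selectedBands", "SelectionResult", function(object) object@selected)
#' @rdname accessors
#' @export
setMethod("rmsecvTrace", "SelectionResult", function(object) object@rmsecvTrace)

# Subset a dataset by sample rows and/or band columns, keeping metadata
# consistent. Used throughout the pipeline (splits, cropping, selections).
#' Subset a SpectralDataset
#'
#' @param x a [SpectralDataset-class].
#' @param i sample (row) indices.
#' @param j band (column) indices.
#' @param ... ignored.
#' @param drop ignored; always a dataset.
#' @return A `SpectralDataset` restricted to the requested samples/bands.
#' @export
setMethod("[", "SpectralDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@X))
  if (missing(j)) j <- seq_len(ncol(x@X))
  SpectralDataset(
    wavelengths = x@wavelengths[j],
    X = x@X[i, j, drop = FALSE],
    y = x@y[i],
    modality = x@modality,
    sampleIds = x@sampleIds[i],
    provenance = x@provenance
  )
})
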
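#' Write a spectral dataset to delimited text
#'
#' CSV dialect: first column `sample_id`, second column `ssc` (Brix), remaining
#' columns named by wavelength in nm with 2-decimal precision.
#'
#' @param ds a [SpectralDataset-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(ds, path) {
  stopifnot(is(ds, "SpectralDataset"))
  df <- data.frame(sample_id = sampleIds(ds), ssc = ssc(ds),
                   check.names = FALSE, stringsAsFactors = FALSE)
  X <- intensities(ds)
  colnames(X) <- sprintf("%.2f", wavelengths(ds))
  utils::write.csv(cbind(df, as.data.frame(X, check.names = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectral dataset from delimited text
#'
#' Expects the [writeSpectra()] dialect. Wavelength columns are reordered to a
#' strictly increasing grid if the file stores them shuffled. Malformed input
#' (non-numeric wavelength header, ragged rows, duplicate wavelengths) is
#' rejected with the offending line or column.
#'
#' @param path input CSV.
#' @param modality `"HSI"` or `"FSI"` tag for the resulting dataset.
#' @return A [SpectralDataset-class].
#' @export
readSpectra <- function(path, modality = c("HSI", "FSI")) {
  modality <- match.arg(modality)
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot(ncol(df) >= 3L, "file must have sample_id, ssc and band columns")
  wlNames <- colnames(df)[-(1:2)]
  wl <- suppressWarnings(as.numeric(wlNames))
  if (anyNA(wl)) {
    bad <- which(is.na(wl))[1]
    stop(sprintf("non-numeric wavelength header in column %d: \"%s\"",
                 bad + 2L, wlNames[bad]), call. = FALSE)
  }
  if (anyDuplicated(wl))
    stop(sprintf("duplicate wavelength %.4f nm in header", wl[anyDuplicated(wl)]),
         call. = FALSE)
  ord <- order(wl)
  X <- as.matrix(df[, -(1:2), drop = FALSE])[, ord, drop = FALSE]
  if (!all(is.finite(X))) {
    bad <- which(!stats::complete.cases(X) |
                 apply(X, 1L, function(r) any(!is.finite(r))))[1]
    stop(sprintf("non-finite intensity value at data line %d", bad + 1L),
         call. = FALSE)
  }
  SpectralDataset(
    wavelengths = wl[ord], X = X, y = as.numeric(df[[2]]),
    modality = modality, sampleIds = as.character(df[[1]]),
    provenance = sprintf("read from %s", path)
  )
}

#' Black-and-white reference calibration
#'
#' Converts raw counts to reflectance with the standard two-reference formula
#' `R = (raw - dark) / (white - dark)`, applied per band.
#'
#' @param raw sample-by-band matrix of raw counts.
#' @param dark dark-current reference, one value per band.
#' @param white white-board reference, one value per band.
#' @return Calibrated matrix of the same shape.
#' @export
bwCalibrate <- function(raw, dark, white) {
  raw <- as.matrix(raw)
  stopIfNot(length(dark) == ncol(raw) && length(white) == ncol(raw),
            "dark and white must have one value per band")
  if (any(white == dark)) {
    stop(sprintf("white equals dark at band %d; calibration undefined",
                 which(white == dark)[1]), call. = FALSE)
  }
  sweep(sweep(raw, 2L, dark, "-"), 2L, white - dark, "/")
}

#' Crop a dataset to its effective wavelength range
#'
#' Retains exactly the bands with `lo <= wavelength <= hi` (closed interval),
#' in their original order. Matches the effective-band selection used before
#' modelling: 420-1000 nm for the reflectance grid, 400-900 nm for the
#' fluorescence grid.
#'
#' @param ds a [SpectralDataset-class].
#' @param lo,hi interval bounds in nm, `lo < hi`.
#' @return The cropped dataset.
#' @export
cropEffective <- function(ds, lo, hi) {
  stopifnot(is(ds, "SpectralDataset"))
  stopIfNot(lo < hi, "lo must be < hi")
  keep <- which(wavelengths(ds) >= lo & wavelengths(ds) <= hi)
  stopIfNot(length(keep) > 0L, "no band inside the requested range")
  ds[, keep]
}

#' Standard normal variate transform
#'
#' Per-spectrum standardisation `(x - mean(x)) / sd(x)` removing multiplicative
#' scatter and additive offset differences between samples.
#'
#' @param ds a [SpectralDataset-class].
#' @param unbiased use the sample (n-1) standard deviation (default) or the
#'   population (n) one.
#' @return Transformed dataset; each spectrum has mean 0 and sd 1.
#' @export
snv <- function(ds, unbiased = TRUE) {
  stopifnot(is(ds, "SpectralDataset"))
  X <- intensities(ds)
  p <- ncol(X)
  m <- rowMeans(X)
  ss <- rowSums((X - m)^2)
  s <- sqrt(ss / (if (unbiased) p - 1 else p))
  if (any(s < 1e-12)) {
    stop(sprintf("constant spectrum (zero spread) for sample(s): %s",
                 paste(sampleIds(ds)[s < 1e-12], collapse = ", ")),
         call. = FALSE)
  }
  replaceIntensities(ds, (X - m) / s, "SNV")
}

#' Detrend correction
#'
#' Subtracts, per spectrum, the least-squares polynomial of degree `polyorder`
#' fitted to intensity against normalised wavelength. Removes smooth baseline
#' drift; degree 2 (the default) removes the quadratic drift typical of
#' scattering baselines.
#'
#' @param ds a [SpectralDataset-class].
#' @param polyorder polynomial degree, `>= 1` and `< nBands`.
#' @return Detrended dataset.
#' @export
detrendSpectra <- function(ds, polyorder = 2L) {
  stopifnot(is(ds, "SpectralDataset"))
  stopIfNot(isCount(polyorder, 1L), "polyorder must be a count >= 1")
  stopIfNot(nBands(ds) > polyorder, "need more bands than polyorder")
  wl <- wavelengths(ds)
  u <- (wl - wl[1]) / (wl[length(wl)] - wl[1])
  basis <- cbind(1, stats::poly(u, degree = polyorder, raw = FALSE))
  Q <- qr.Q(qr(basis))
  X <- intensities(ds)
  replaceIntensities(ds, X - (X %*% Q) %*% t(Q),
                     sprintf("DT(order=%d)", polyorder))
}

# Reflect-pad a spectrum matrix by m bands on each side (reflection about the
# edge point, edge not repeated), then convolve rows with kernel h.
convolveRows <- function(X, h) {
  m <- (length(h) - 1L) %/% 2L
  p <- ncol(X)
  stopIfNot(p > m, "window too large for the number of bands")
  idx <- c((m + 1L):2L, seq_len(p), (p - 1L):(p - m))
  Xp <- X[, idx, drop = FALSE]
  out <- matrix(0, nrow(X), p)
  for (k in seq_along(h)) {
    out <- out + h[k] * Xp[, k:(k + p - 1L), drop = FALSE]
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing via the central Savitzky-Golay
#' convolution kernel (coefficients from [signal::sgolay()]); spectrum edges
#' are handled by reflect-padding so the band count is preserved.
#'
#' @param ds a [SpectralDataset-class].
#' @param window odd window width in bands (default 9).
#' @param polyorder local polynomial degree, `< window` (default 2).
#' @return Smoothed dataset.
#' @export
sgSmooth <- function(ds, window = 9L, polyorder = 2L) {
  stopifnot(is(ds, "SpectralDataset"))
  stopIfNot(isCount(window, 3L) && window %% 2L == 1L, "window must be odd and >= 3")
  stopIfNot(isCount(polyorder, 0L) && polyorder < window, "polyorder must be < window")
  stopIfNot(window <= nBands(ds), "window exceeds the number of bands")
  h <- signal::sgolay(p = polyorder, n = window)[(window + 1L) %/% 2L, ]
  replaceIntensities(ds, convolveRows(intensities(ds), as.numeric(h)),
                     sprintf("SG(window=%d,order=%d)", window, polyorder))
}

#' Kernel smoothing (Gaussian window, boxcar, exponential)
#'
#' `gaussian`: normalised Gaussian-kernel convolution (sd `gaussianSd` bands,
#' truncated at `window`); `boxcar`: moving average of width `window`;
#' `exponential`: causal first-order recursion
#' `x'_i = alpha * x_i + (1 - alpha) * x'_{i-1}` with `x'_1 = x_1`, run along
#' increasing wavelength (`direction = "forward"`), or averaged with the
#' reversed pass (`"symmetric"`). Convolution kinds use reflect-padding.
#'
#' @param ds a [SpectralDataset-class].
#' @param kind `"gaussian"`, `"boxcar"` or `"exponential"`.
#' @param window odd window width in bands (gaussian/boxcar).
#' @param gaussianSd Gaussian kernel sd in bands.
#' @param alpha exponential smoothing constant in `(0, 1]`; `alpha = 1` is the
#'   identity.
#' @param direction pass direction for the exponential recursion.
#' @return Smoothed dataset.
#' @export
kernelSmooth <- function(ds, kind = c("gaussian", "boxcar", "exponential"),
                         window = 9L, gaussianSd = 2, alpha = 0.3,
                         direction = c("forward", "symmetric")) {
  stopifnot(is(ds, "SpectralDataset"))
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  X <- intensities(ds)
  if (kind == "exponential") {
    stopIfNot(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 1,
              "alpha must be in (0, 1]")
    out <- expSmoothRows(X, alpha)
    if (direction == "symmetric") {
      rev2 <- expSmoothRows(X[, rev(seq_len(ncol(X))), drop = FALSE], alpha)
      out <- (out + rev2[, rev(seq_len(ncol(X))), drop = FALSE]) / 2
    }
    return(replaceIntensities(ds, out, sprintf("ES(alpha=%g,%s)", alpha, direction)))
  }
  stopIfNot(isCount(window, 3L) && window %% 2L == 1L, "window must be odd and >= 3")
  stopIfNot(window <= nBands(ds), "window exceeds the number of bands")
  m <- (window - 1L) %/% 2L
  h <- if (kind == "boxcar") {
    rep(1 / window, window)
  } else {
    stopIfNot(is.numeric(gaussianSd) && gaussianSd > 0, "gaussianSd must be > 0")
    w <- exp(-((-m:m)^2) / (2 * gaussianSd^2))
    w / sum(w)
  }
  replaceIntensities(ds, convolveRows(X, h),
                     sprintf("%s(window=%d%s)",
                             if (kind == "boxcar") "BS" else "GWS", window,
                             if (kind == "gaussian") sprintf(",sd=%g", gaussianSd) else ""))
}

expSmoothRows <- function(X, alpha) {
  out <- X
  for (j in seq_len(ncol(X))[-1]) {
    out[, j] <- alpha * X[, j] + (1 - alpha) * out[, j - 1L]
  }
  out
}

replaceIntensities <- function(ds, X, tag) {
  SpectralDataset(
    wavelengths = wavelengths(ds), X = X, y = ssc(ds),
    modality = modality(ds), sampleIds = sampleIds(ds),
    provenance = paste(ds@provenance, tag, sep = " | ")
  )
}

#' Pre-processing specification
#'
#' Parameter bag naming one of the seven pre-processing operators: `raw`
#' (identity), `SNV`, `DT` (detrend), `SG` (Savitzky-Golay), `GWS` (Gaussian
#' window), `BS` (boxcar), `ES` (exponential).
#'
#' @param method operator name.
#' @param window odd window in bands (SG/GWS/BS), default 9.
#' @param polyorder polynomial degree (SG/DT), default 2.
#' @param alpha exponential constant in `(0, 1]`, default 0.3.
#' @param gaussianSd Gaussian kernel sd in bands, default 2.
#' @return A validated `PreprocessSpec` list.
#' @export
preprocessSpec <- function(method = c("raw", "SNV", "DT", "SG", "GWS", "BS", "ES"),
                           window = 9L, polyorder = 2L, alpha = 0.3,
                           gaussianSd = 2) {
  method <- match.arg(method)
  if (method %in% c("SG", "GWS", "BS"))
    stopIfNot(isCount(window, 3L) && window %% 2L == 1L, "window must be odd and >= 3")
  if (method == "SG")
    stopIfNot(polyorder < window, "polyorder must be < window")
  if (method == "ES")
    stopIfNot(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  structure(list(method = method, window = as.integer(window),
                 polyorder = as.integer(polyorder), alpha = alpha,
                 gaussianSd = gaussianSd),
            class = "PreprocessSpec")
}

#' Apply a pre-processing specification
#'
#' Dispatches to the operator named in `spec`; `raw` returns the dataset
#' unchanged (provenance annotated).
#'
#' @param ds a [SpectralDataset-class].
#' @param spec a [preprocessSpec()].
#' @return The pre-processed dataset.
#' @export
applyPreprocess <- function(ds, spec) {
  stopifnot(is(ds, "SpectralDataset"), inherits(spec, "PreprocessSpec"))
  switch(spec$method,
    raw = replaceIntensities(ds, intensities(ds), "raw"),
    SNV = snv(ds),
    DT = detrendSpectra(ds, spec$polyorder),
    SG = sgSmooth(ds, spec$window, spec$polyorder),
    GWS = kernelSmooth(ds, "gaussian", spec$window, gaussianSd = spec$gaussianSd),
    BS = kernelSmooth(ds, "boxcar", spec$window),
    ES = kernelSmooth(ds, "exponential", alpha = spec$alpha),
    stop(sprintf("unknown pre-processing method: %s", spec$method), call. = FALSE)
  )
}
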
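#' Configuration for the synthetic spectra generator
#'
#' Builds the parameter set of the SSC-to-spectrum forward model. Defaults
#' emulate the study conditions of a 90-fruit kiwifruit assay: SSC mean
#' 11.04 Brix, sd 1.79, range 6.50-15.35; a 229-band reflectance (HSI) grid on
#' 420-1000 nm with pigment absorption troughs near 450 and 670 nm and an
#' SSC-linked C-H/O-H overtone trough near 980 nm; a 102-band fluorescence
#' (FSI) grid on 400-900 nm with a nuisance emission peak near 510 nm and
#' SSC-linked peaks near 690 and 740 nm.
#'
#' @param modality `"HSI"` (reflectance, absorption troughs) or `"FSI"`
#'   (fluorescence, emission peaks).
#' @param nSamples number of fruit.
#' @param nBands number of bands; default 229 (HSI) / 102 (FSI).
#' @param wavelengthRange `(lo, hi)` nm; default `c(420, 1000)` / `c(400, 900)`.
#' @param sscMean,sscSd,sscRange SSC distribution (Brix); a normal truncated to
#'   `sscRange` by rejection.
#' @param informativeCenters nm positions of spectral features.
#' @param informativeWidths Gaussian sd of each feature in nm; default 20 nm
#'   (HSI) / 30 nm (FSI).
#' @param sscLinked logical per feature: `TRUE` features scale with the
#'   sample's SSC, others carry an independent nuisance concentration (pigment
#'   proxy) of the same magnitude.
#' @param effectSize per-Brix feature amplitude (intensity units per Brix);
#'   default 0.02 (HSI) / 0.045 (FSI) — overtone absorption troughs are a
#'   subtle modulation of reflectance, while filtered emission intensity
#'   responds more directly to the analyte.
#' @param noiseSd white-noise sd (intensity units).
#' @param scatterSd sd of the multiplicative sample gain `g_i ~ 1 + N(0, .)`;
#'   default 0.05 (HSI) / 0.03 (FSI).
#' @param baselineAmp sd of the random quadratic baseline coefficients
#'   (intensity units).
#' @param seed integer seed controlling every random draw.
#' @return A validated `GeneratorConfig` list.
#' @export
generatorConfig <- function(modality = c("HSI", "FSI"),
                            nSamples = 90L,
                            nBands = NULL,
                            wavelengthRange = NULL,
                            sscMean = 11.04,
                            sscSd = 1.79,
                            sscRange = c(6.50, 15.35),
                            informativeCenters = NULL,
                            informativeWidths = NULL,
                            sscLinked = NULL,
                            effectSize = NULL,
                            noiseSd = 0.01,
                            scatterSd = NULL,
                            baselineAmp = 0.01,
                            seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(effectSize)) effectSize <- if (modality == "HSI") 0.02 else 0.045
  if (is.null(scatterSd)) scatterSd <- if (modality == "HSI") 0.05 else 0.03
  if (is.null(nBands)) nBands <- if (modality == "HSI") 229L else 102L
  if (is.null(wavelengthRange))
    wavelengthRange <- if (modality == "HSI") c(420, 1000) else c(400, 900)
  if (is.null(informativeCenters))
    informativeCenters <- if (modality == "HSI") c(450, 670, 980) else c(510, 690, 740)
  if (is.null(informativeWidths))
    informativeWidths <- rep(if (modality == "HSI") 20 else 30,
                             length(informativeCenters))
  if (is.null(sscLinked))
    sscLinked <- if (modality == "HSI") c(FALSE, FALSE, TRUE) else c(FALSE, TRUE, TRUE)

  stopIfNot(isCount(nSamples, 1L), "nSamples must be a positive count")
  stopIfNot(isCount(nBands, 2L), "nBands must be a count >= 2")
  stopIfNot(length(wavelengthRange) == 2L && wavelengthRange[1] < wavelengthRange[2],
            "wavelengthRange must be strictly increasing")
  stopIfNot(length(sscRange) == 2L && sscRange[1] < sscRange[2],
            "sscRange must satisfy lo < hi")
  stopIfNot(sscSd >= 0, "sscSd must be >= 0")
  stopIfNot(all(informativeCenters >= wavelengthRange[1] &
                informativeCenters <= wavelengthRange[2]),
            "informativeCenters must lie inside wavelengthRange")
  stopIfNot(length(informativeWidths) == length(informativeCenters) &&
            all(informativeWidths > 0),
            "informativeWidths must be positive, one per center")
  stopIfNot(length(sscLinked) == length(informativeCenters),
            "sscLinked must have one entry per center")
  stopIfNot(noiseSd >= 0 && scatterSd >= 0 && baselineAmp >= 0,
            "noiseSd, scatterSd and baselineAmp must be >= 0")

  structure(
    list(
      modality = modality, nSamples = as.integer(nSamples),
      nBands = as.integer(nBands), wavelengthRange = wavelengthRange,
      sscMean = sscMean, sscSd = sscSd, sscRange = sscRange,
      informativeCenters = informativeCenters,
      informativeWidths = informativeWidths,
      sscLinked = as.logical(sscLinked),
      effectSize = effectSize, noiseSd = noiseSd, scatterSd = scatterSd,
      baselineAmp = baselineAmp, seed = as.integer(seed)
    ),
    class = "GeneratorConfig"
  )
}

#' Draw reference SSC values
#'
#' Truncated-normal sampling by rejection: draws `N(sscMean, sscSd)` and keeps
#' values inside `sscRange`. Rejection slightly shifts the realised moments
#' towards the interval centre relative to the nominal mean/sd; with `sscSd =
#' 0` the vector is constant at `sscMean` (which must then lie inside the
#' range).
#'
#' @param cfg a [generatorConfig()] object.
#' @return Numeric vector of length `nSamples`, all inside `sscRange` (Brix).
#' @export
sampleSSC <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  if (cfg$sscSd == 0) {
    stopIfNot(cfg$sscMean >= cfg$sscRange[1] && cfg$sscMean <= cfg$sscRange[2],
              "sscMean must lie inside sscRange when sscSd = 0")
    return(rep(cfg$sscMean, cfg$nSamples))
  }
  withSeed(cfg$seed, {
    out <- numeric(0)
    while (length(out) < cfg$nSamples) {
      draw <- stats::rnorm(max(cfg$nSamples * 2L, 32L), cfg$sscMean, cfg$sscSd)
      out <- c(out, draw[draw >= cfg$sscRange[1] & draw <= cfg$sscRange[2]])
    }
    out[seq_len(cfg$nSamples)]
  })
}

# The wavelength grid of a config; rounded to 2 decimals so the CSV writer
# (2-decimal wavelength header) round-trips exactly. Steps are ~2.5 nm (HSI)
# and ~5 nm (FSI), so rounding keeps the grid strictly increasing.
generatorGrid <- function(cfg) {
  round(seq(cfg$wavelengthRange[1], cfg$wavelengthRange[2],
            length.out = cfg$nBands), 2)
}

# Smooth modality-specific base curve on normalised wavelength u in [0, 1].
baseCurve <- function(u, modality) {
  if (modality == "HSI") 0.45 + 0.30 * sin(pi * u) else 0.12 + 0.06 * u
}

#' Generate spectra from SSC values
#'
#' Forward model per sample `i` and band `lambda`:
#' `X_i(lambda) = g_i * (B(lambda) + sum_k sgn * A_k(lambda) * c_ik)
#'  + d_i(lambda) + eps_i(lambda)`
#' where `B` is a smooth base curve, `A_k` are unit-height Gaussians at the
#' informative centers, `sgn` is -1 for HSI (absorption troughs) and +1 for FSI
#' (emission peaks), `c_ik = effectSize * SSC_i` for SSC-linked features and
#' `effectSize * N(sscMean, sscSd)` (an independent pigment-like nuisance
#' concentration) otherwise, `g_i ~ 1 + N(0, scatterSd)` is multiplicative
#' scatter, `d_i` a random quadratic baseline and `eps` white noise.
#'
#' @param cfg a [generatorConfig()].
#' @param sscValues SSC vector of length `nSamples` (Brix).
#' @return A [SpectralDataset-class].
#' @export
generateSpectra <- function(cfg, sscValues) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  stopIfNot(length(sscValues) == cfg$nSamples,
            "length(sscValues) must equal cfg$nSamples")
  wl <- generatorGrid(cfg)
  u <- (wl - wl[1]) / (wl[cfg$nBands] - wl[1])
  B <- baseCurve(u, cfg$modality)
  sgn <- if (cfg$modality == "HSI") -1 else 1
  nK <- length(cfg$informativeCenters)
  A <- vapply(seq_len(nK), function(k) {
    exp(-(wl - cfg$informativeCenters[k])^2 / (2 * cfg$informativeWidths[k]^2))
  }, numeric(cfg$nBands)) # nBands x nK

  withSeed(deriveSeed(cfg$seed, 1L), {
    n <- cfg$nSamples
    conc <- matrix(0, n, nK)
    for (k in seq_len(nK)) {
      conc[, k] <- if (cfg$sscLinked[k]) {
        cfg$effectSize * sscValues
      } else {
        cfg$effectSize * stats::rnorm(n, cfg$sscMean, cfg$sscSd)
      }
    }
    g <- 1 + stats::rnorm(n, 0, cfg$scatterSd)
    baseCoef <- matrix(stats::rnorm(3L * n, 0, cfg$baselineAmp), n, 3L)
    drift <- baseCoef %*% rbind(rep(1, cfg$nBands), u, u^2)
    eps <- matrix(stats::rnorm(n * cfg$nBands, 0, cfg$noiseSd), n, cfg$nBands)

    signal <- matrix(B, n, cfg$nBands, byrow = TRUE) + sgn * conc %*% t(A)
    X <- signal * g + drift + eps
    SpectralDataset(
      wavelengths = wl, X = X, y = sscValues, modality = cfg$modality,
      provenance = sprintf(
        "synthetic %s: n=%d, bands=%d [%g-%g nm], effectSize=%g, noiseSd=%g, scatterSd=%g, baselineAmp=%g, seed=%d",
        cfg$modality, n, cfg$nBands, cfg$wavelengthRange[1],
        cfg$wavelengthRange[2], cfg$effectSize, cfg$noiseSd, cfg$scatterSd,
        cfg$baselineAmp, cfg$seed
      )
    )
  })
}

#' Generate a complete synthetic dataset
#'
#' Composes [sampleSSC()] and [generateSpectra()]; identical `(cfg, seed)`
#' yields bitwise-identical datasets.
#'
#' @param cfg a [generatorConfig()].
#' @return A [SpectralDataset-class].
#' @examples
#' ds <- makeDataset(generatorConfig("HSI", seed = 1))
#' ds
#' @export
makeDataset <- function(cfg) {
  generateSpectra(cfg, sampleSSC(cfg))
}
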
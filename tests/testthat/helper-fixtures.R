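# Small fixture builders shared across test files.

# A compact planted-signal dataset: fewer bands than the full default grids so
# unit tests stay fast, same forward model.
smallHsiConfig <- function(seed = 1L, nSamples = 60L, ...) {
  generatorConfig("HSI", nSamples = nSamples, nBands = 60L,
                  wavelengthRange = c(420, 1000), seed = seed, ...)
}

# Pure-noise dataset: no SSC-linked feature at all.
nullConfig <- function(seed = 1L, nSamples = 60L, nBands = 40L) {
  generatorConfig("HSI", nSamples = nSamples, nBands = nBands,
                  wavelengthRange = c(420, 1000), effectSize = 0,
                  seed = seed)
}

# Band index nearest a wavelength.
bandNearest <- function(ds, nm) which.min(abs(wavelengths(ds) - nm))

# Did a selection hit the planted band within +/- tol bands?
recovered <- function(selected, target, tol = 2L) {
  any(abs(selected - target) <= tol)
}

# Calibration matrix + SSC of the default study-scale pipeline front end.
preppedTrain <- function(modality = "HSI", seed = 1L,
                         prep = if (modality == "HSI") "BS" else "SG") {
  ds <- makeDataset(generatorConfig(modality, seed = seed))
  pp <- applyPreprocess(ds, preprocessSpec(prep))
  sp <- ksSplit(pp)
  list(ds = ds, train = sp$train, test = sp$test,
       X = intensities(sp$train), y = ssc(sp$train),
       target = if (modality == "HSI") bandNearest(ds, 980) else bandNearest(ds, 740))
}
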
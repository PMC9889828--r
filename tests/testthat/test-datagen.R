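test_that("SSC sampling respects the truncated-normal contract", {
  cfg <- generatorConfig("HSI", nSamples = 90L, sscMean = 11.04, sscSd = 1.79,
                         sscRange = c(6.50, 15.35), seed = 1L)
  y <- sampleSSC(cfg)
  expect_length(y, 90L)
  expect_true(all(y >= 6.50 & y <= 15.35))
  expect_identical(y, sampleSSC(cfg))

  # zero-variance case
  cfg0 <- generatorConfig("HSI", nSamples = 10L, sscSd = 0, seed = 1L)
  expect_identical(sampleSSC(cfg0), rep(11.04, 10))

  # Monte-Carlo mean at large n
  cfgBig <- generatorConfig("HSI", nSamples = 10000L, sscMean = 11,
                            sscSd = 1.79, seed = 7L)
  expect_lt(abs(mean(sampleSSC(cfgBig)) - 11), 0.1)

  # truncation holds across seeds
  for (s in 1:10) {
    ys <- sampleSSC(generatorConfig("HSI", nSamples = 50L, seed = s))
    expect_true(min(ys) >= 6.50 && max(ys) <= 15.35)
  }

  expect_error(generatorConfig("HSI", sscRange = c(10, 10)), "lo < hi")
})

test_that("generated datasets have the study-scale shapes and valid slots", {
  hsi <- makeDataset(generatorConfig("HSI", seed = 1L))
  expect_identical(dim(intensities(hsi)), c(90L, 229L))
  expect_identical(range(wavelengths(hsi)), c(420, 1000))

  fsi <- makeDataset(generatorConfig("FSI", seed = 1L))
  expect_identical(dim(intensities(fsi)), c(90L, 102L))
  expect_identical(range(wavelengths(fsi)), c(400, 900))
  expect_length(wavelengths(fsi), 102L)

  expect_true(validObject(hsi))
  expect_true(all(is.finite(intensities(hsi))))
})

test_that("generation is deterministic in (config, seed)", {
  cfg <- generatorConfig("HSI", seed = 11L)
  a <- makeDataset(cfg)
  b <- makeDataset(cfg)
  expect_identical(intensities(a), intensities(b))
  expect_identical(ssc(a), ssc(b))
  c <- makeDataset(generatorConfig("HSI", seed = 12L))
  expect_false(identical(intensities(a), intensities(c)))
})

test_that("the planted SSC band carries the signal", {
  ds <- makeDataset(generatorConfig("HSI", seed = 1L))
  target <- bandNearest(ds, 980)
  co <- abs(stats::cor(intensities(ds), ssc(ds)))
  expect_gt(co[target], stats::median(co))

  # noise-free limit: single-band regression explains y perfectly
  clean <- makeDataset(generatorConfig("HSI", seed = 2L, noiseSd = 0,
                                       scatterSd = 0, baselineAmp = 0))
  b <- bandNearest(clean, 980)
  # suppressWarnings: summary.lm warns on an essentially perfect fit, which
  # is exactly the property under test
  r2 <- suppressWarnings(
    summary(stats::lm(ssc(clean) ~ intensities(clean)[, b]))$r.squared
  )
  expect_gt(r2, 0.999)
})

test_that("with no variation sources all spectra are identical", {
  cfg <- generatorConfig("HSI", nSamples = 8L, nBands = 30L,
                         informativeCenters = c(980), informativeWidths = 20,
                         sscLinked = TRUE, effectSize = 0, noiseSd = 0,
                         scatterSd = 0, baselineAmp = 0, seed = 3L)
  ds <- makeDataset(cfg)
  X <- intensities(ds)
  expect_true(all(apply(X, 2L, function(col) max(col) - min(col)) == 0))
})

test_that("without SSC-linked features band correlations are null", {
  cfg <- generatorConfig("HSI", nSamples = 90L, effectSize = 0, seed = 5L)
  ds <- makeDataset(cfg)
  X <- intensities(ds)
  y <- ssc(ds)
  obs <- mean(abs(stats::cor(X, y)))
  # permutation null for the same statistic
  set.seed(99)
  perm <- replicate(60, mean(abs(stats::cor(X, sample(y)))))
  expect_lte(obs, stats::quantile(perm, 0.99))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generatorConfig("HSI", nBands = 1L), "nBands")
  expect_error(generatorConfig("HSI", wavelengthRange = c(1000, 420)),
               "strictly increasing")
  expect_error(generatorConfig("HSI", informativeCenters = c(450, 670, 1100)),
               "inside wavelengthRange")
  expect_error(generatorConfig("HSI", noiseSd = -1), ">= 0")
  cfg <- generatorConfig("HSI", nSamples = 5L)
  expect_error(generateSpectra(cfg, 1:4), "nSamples")
})
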
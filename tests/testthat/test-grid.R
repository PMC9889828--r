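# Grid tests run on compact synthetic data (45-60 samples, 60 bands) so the
# whole file stays inside a few tens of seconds.

test_that("the pre-processing comparison emits one row per operator", {
  ds <- makeDataset(smallHsiConfig(seed = 2L, nSamples = 45L))
  tab <- runPrepComparison(ds, maxLv = 10L, masterSeed = 2L)
  expect_identical(nrow(tab), 7L)
  expect_identical(tab$pipeline,
                   c("raw", "SNV", "DT", "SG", "GWS", "BS", "ES"))
  expect_identical(sum(tab$best), 1L)
  expect_identical(which(tab$best), which.max(tab$RPD))
  expect_true(all(tab$RMSEP > 0))
})

test_that("smoothing does not catastrophically hurt clean synthetic data", {
  deltas <- vapply(1:5, function(s) {
    ds <- makeDataset(smallHsiConfig(seed = s, nSamples = 45L))
    tab <- runPrepComparison(ds, methods = c("raw", "SG", "GWS", "BS", "ES"),
                             maxLv = 10L, masterSeed = s)
    min(tab$RPD[-1]) - tab$RPD[1]
  }, 0)
  expect_gte(stats::median(deltas), -0.2)
})

test_that("the selector-by-model grid is complete, deterministic and subset-consistent", {
  ds <- makeDataset(smallHsiConfig(seed = 5L, nSamples = 60L))
  sels <- list(
    CARS = selectorParams("CARS", maxLv = 8L, kFolds = 5L, nSampling = 40L,
                          seed = 5L),
    MASS = selectorParams("MASS", maxLv = 8L, kFolds = 5L, nSampling = 60L,
                          seed = 5L),
    `MASS-Boss` = list(
      first = selectorParams("MASS", maxLv = 8L, kFolds = 5L, nSampling = 60L,
                             seed = 5L),
      then = selectorParams("Boss", maxLv = 8L, kFolds = 5L, nSampling = 60L,
                            seed = 51L)
    )
  )
  g1 <- runGrid(ds, preprocessSpec("BS"), sels, models = c("PLSR", "ELM"),
                masterSeed = 7L, elmRange = c(2L, 5L, 10L, 20L))
  expect_identical(nrow(g1$results), 6L) # 3 selectors x 2 models
  expect_true(all(!g1$results$failed))

  g2 <- runGrid(ds, preprocessSpec("BS"), sels, models = c("PLSR", "ELM"),
                masterSeed = 7L, elmRange = c(2L, 5L, 10L, 20L))
  expect_equal(g1$results, g2$results)

  # cascade rows never use more features than their primary selector rows
  nf <- tapply(g1$results$nFeatures, g1$results$pipeline, unique)
  expect_lte(nf[["MASS-Boss"]], nf[["MASS"]])

  # best-per-model summary is the argmax-RPD row of that model's cells
  for (m in unique(g1$best$model)) {
    cells <- g1$results[g1$results$model == m, ]
    expect_equal(g1$best$RPD[g1$best$model == m], max(cells$RPD))
  }

  # one shared split for every cell
  expect_identical(length(g1$split$trainIdx), 40L)
  expect_identical(length(g1$split$testIdx), 20L)
})

test_that("a failing cell is reported, not dropped", {
  ds <- makeDataset(smallHsiConfig(seed = 8L, nSamples = 45L))
  sels <- list(none = selectorParams("none", maxLv = 5L, kFolds = 5L))
  g <- runGrid(ds, preprocessSpec("raw"), sels, models = c("PLSR", "bogus"),
               masterSeed = 1L)
  expect_identical(nrow(g$results), 2L)
  expect_true(g$results$failed[g$results$model == "bogus"])
  expect_false(g$results$failed[g$results$model == "PLSR"])
})
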
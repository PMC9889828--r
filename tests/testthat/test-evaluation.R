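test_that("metric definitions hold on worked examples", {
  y <- c(1, 2, 3, 4)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 4)), 0)
  expect_equal(rSquared(c(0, 2), c(1, 1)), 0)

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  f <- c(1.3, 2.1, 2.8, 4.4)
  expect_equal(rmse(y, y + 3 * (f - y)), 3 * rmse(y, f))

  yt <- c(10, 11, 12, 13)
  expect_equal(rpd(yt, stats::sd(yt) / 2), 2)
  expect_equal(rpd(yt, stats::sd(yt)), 1)
  expect_error(rpd(yt, 0), "> 0")

  expect_identical(gradeRPD(c(1.3, 1.7, 2.3)), c("poor", "average", "good"))
  expect_identical(gradeRPD(c(1.4, 2.0)), c("average", "good")) # boundaries
})

test_that("metric identities hold on random fixtures", {
  set.seed(10)
  for (i in 1:10) {
    y <- rnorm(20, 11, 1.8)
    f <- y + rnorm(20, 0, 0.5)
    # definitional identity linking RPD, sd and RMSE
    expect_equal(rpd(y, rmse(y, f)), stats::sd(y) / rmse(y, f))
    # shift invariance
    expect_equal(rSquared(y + 5, f + 5), rSquared(y, f))
    expect_equal(rmse(y + 5, f + 5), rmse(y, f))
  }
})

test_that("evaluation reports are internally consistent", {
  ds <- makeDataset(smallHsiConfig(seed = 6L, nSamples = 45L))
  sp <- ksSplit(ds)
  X <- intensities(sp$train)
  y <- ssc(sp$train)
  fit <- fitPLSR(X, y, 5)
  # self-evaluation: prediction metrics equal calibration metrics
  self <- evaluateModel(fit, sp$train, sp$train, NULL)
  expect_equal(self$R2p, self$R2c)
  expect_equal(self$RMSEP, self$RMSEC)

  rep <- evaluateModel(fit, sp$train, sp$test, NULL, pipeline = "raw/none")
  expect_gte(rep$RMSEC, 0)
  expect_gte(rep$RMSEP, 0)
  expect_lte(rep$R2c, 1)
  expect_identical(rep$nFeatures, nBands(ds))
  expect_identical(rep$grade, gradeRPD(rep$RPD))
  expect_equal(rep$RPD, stats::sd(ssc(sp$test)) / rep$RMSEP)

  # a (near-)constant predictor cannot beat the prediction-set mean
  constFit <- fitLSSVM(X, y, gamma = 1e-3, sigma2 = 1e-4)
  constRep <- evaluateModel(constFit, sp$train, sp$test, NULL)
  expect_lte(constRep$R2p, 1e-6)

  # band-count mismatch between fit and selection is rejected
  selBad <- runSelector(X[, 1:10], y,
                        selectorParams("none", maxLv = 3L, kFolds = 5L))
  expect_error(evaluateModel(fit, sp$train, sp$test, selBad), "match")
})
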
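# Unit-scale selector checks run on a compact 60-band planted-signal dataset;
# the full study-scale recovery suite lives in test-acceptance.R.

smallTrain <- function(seed = 1L) {
  ds <- makeDataset(smallHsiConfig(seed = seed, nSamples = 60L))
  list(X = intensities(ds), y = ssc(ds), target = bandNearest(ds, 980))
}

selectorFor <- function(method, seed = 1L, n = 60L) {
  selectorParams(method, maxLv = 8L, kFolds = 5L, nSampling = n, seed = seed)
}

test_that("every selector returns a valid, reproducible SelectionResult", {
  tr <- smallTrain(1L)
  for (m in c("Boss", "CARS", "IVSO", "IVISSA", "MASS")) {
    p <- selectorFor(m, seed = 3L)
    r1 <- runSelector(tr$X, tr$y, p)
    expect_s4_class(r1, "SelectionResult")
    expect_true(validObject(r1))
    expect_identical(r1@method, m)
    expect_equal(r1@rmsecvTrace[r1@bestIteration], min(r1@rmsecvTrace))
    expect_true(all(r1@weightsFinal >= 0))
    expect_true(all(selectedBands(r1) >= 1L &
                    selectedBands(r1) <= ncol(tr$X)))
    r2 <- runSelector(tr$X, tr$y, p)
    expect_identical(selectedBands(r1), selectedBands(r2))
    expect_identical(r1@rmsecvTrace, r2@rmsecvTrace)
  }
})

test_that("selectors recover the planted band on compact data", {
  hits <- sapply(c("Boss", "CARS", "IVSO", "IVISSA", "MASS"), function(m) {
    tr <- smallTrain(7L)
    r <- runSelector(tr$X, tr$y, selectorFor(m, seed = 7L))
    recovered(selectedBands(r), tr$target)
  })
  expect_true(all(hits))
})

test_that("the CARS exponential decay hits its boundary conditions", {
  p <- 229L
  N <- 100L
  ratio <- specbrix:::carsRetainRatio(1:N, N, p)
  expect_equal(ratio[1], 1)             # all p bands at the first run
  expect_equal(ceiling(ratio[N] * p), 2L) # two bands at the last run
  expect_true(all(diff(ceiling(ratio * p)) <= 0))
})

test_that("CARS trace reflects a shrinking retained set", {
  tr <- smallTrain(4L)
  r <- runCars(tr$X, tr$y, selectorFor("CARS", seed = 4L, n = 40L))
  expect_gte(length(selectedBands(r)), 1L)
  expect_lte(length(selectedBands(r)), ncol(tr$X))
  expect_equal(r@rmsecvTrace[r@bestIteration], min(r@rmsecvTrace))
})

test_that("a single-band dataset is passed through untouched", {
  set.seed(5)
  X <- matrix(rnorm(30), 30, 1)
  y <- 2 * X[, 1] + rnorm(30, 0, 0.1)
  for (m in c("Boss", "CARS", "IVSO", "IVISSA", "MASS")) {
    r <- runSelector(X, y, selectorParams(m, maxLv = 1L, kFolds = 5L,
                                          nSampling = 10L, seed = 1L))
    expect_identical(selectedBands(r), 1L)
    expect_gte(length(r@rmsecvTrace), 1L)
  }
})

test_that("selection on pure noise does not collapse the RMSECV", {
  # guard against sub-model selection bias bugs: the best RMSECV should not
  # sit materially below sd(y); median over seeds, per selector
  for (m in c("Boss", "MASS")) {
    ratios <- vapply(1:5, function(s) {
      ds <- makeDataset(nullConfig(seed = s))
      X <- intensities(ds)
      y <- ssc(ds)
      r <- runSelector(X, y, selectorParams(m, maxLv = 8L, kFolds = 5L,
                                            nSampling = 60L, seed = s))
      min(r@rmsecvTrace) / stats::sd(y)
    }, 0)
    expect_gt(stats::median(ratios), 0.75)
  }
})

test_that("cascading restricts to a subset of the first stage", {
  tr <- smallTrain(3L)
  first <- selectorFor("MASS", seed = 3L)
  then <- selectorFor("Boss", seed = 31L)
  cas <- runCascade(tr$X, tr$y, first, then)
  solo <- runMass(tr$X, tr$y, first)
  expect_true(all(selectedBands(cas) %in% selectedBands(solo)))
  expect_identical(cas@method, "MASS-Boss")

  # identity second stage reproduces the first stage
  keepAll <- selectorParams("none", maxLv = 8L, kFolds = 5L, seed = 32L)
  casId <- runCascade(tr$X, tr$y, first, keepAll)
  expect_identical(selectedBands(casId), selectedBands(solo))

  # degenerate first stage: single band -> second stage skipped with a flag
  set.seed(6)
  X1 <- matrix(rnorm(30), 30, 1)
  y1 <- X1[, 1] + rnorm(30, 0, 0.1)
  expect_warning(
    deg <- runCascade(X1, y1, selectorParams("MASS", maxLv = 1L, kFolds = 5L,
                                             nSampling = 10L, seed = 1L),
                      then),
    "skipped"
  )
  expect_true(isTRUE(deg@params$cascadeSkipped))
})

test_that("selection summaries report the share of the grid", {
  expect_equal(selectionSummary(19, 229)$percent, 8.3)
  expect_equal(selectionSummary(31, 102)$percent, 30.4)
  expect_equal(selectionSummary(0, 229)$percent, 0)
  tr <- smallTrain(1L)
  r <- runSelector(tr$X, tr$y, selectorFor("CARS", seed = 1L, n = 30L))
  s <- selectionSummary(r, ncol(tr$X))
  expect_identical(s$nSelected, length(selectedBands(r)))
})

test_that("selection results serialise to JSON with 0-based indices", {
  tr <- smallTrain(1L)
  r <- runSelector(tr$X, tr$y, selectorFor("CARS", seed = 1L, n = 30L))
  path <- withr::local_tempfile(fileext = ".json")
  wl <- seq(420, 1000, length.out = 60)
  writeSelection(r, wl, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(as.integer(back$selected), selectedBands(r) - 1L)
  expect_equal(back$selected_wavelengths_nm, wl[selectedBands(r)])
  expect_identical(back$method, "CARS")
})
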
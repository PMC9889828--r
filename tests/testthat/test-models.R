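test_that("PLSR recovers exact low-rank relations and matches OLS at full rank", {
  set.seed(1)
  x1 <- rnorm(15)
  X <- cbind(x1, rnorm(15), rnorm(15))
  yExact <- 2 * x1
  fit <- fitPLSR(X[, 1, drop = FALSE], yExact, 1)
  expect_lt(fit@trainSummary[["RMSEC"]], 1e-10)
  expect_equal(fit@learned$coef, 2, tolerance = 1e-8)

  # full latent dimension == ordinary least squares on well-conditioned data
  set.seed(2)
  X10 <- matrix(rnorm(30), 10, 3)
  y10 <- as.numeric(X10 %*% c(1, -2, 3)) + rnorm(10, 0, 0.2)
  pls3 <- fitPLSR(X10, y10, 3)
  ols <- stats::lm(y10 ~ X10)
  expect_equal(predict(pls3, X10), unname(stats::fitted(ols)),
               tolerance = 1e-8)

  # centering identity: the mean spectrum predicts the mean response
  for (lv in 1:3) {
    f <- fitPLSR(X10, y10, lv)
    expect_equal(predict(f, matrix(colMeans(X10), 1)), mean(y10),
                 tolerance = 1e-8)
  }
  expect_error(fitPLSR(X10, rep(5, 10), 2), "zero variance")
})

test_that("ELM is deterministic and solves the output layer exactly", {
  set.seed(3)
  X <- matrix(rnorm(25 * 4), 25)
  y <- as.numeric(X %*% c(1, 2, -1, 0.5)) + rnorm(25, 0, 0.1)
  f1 <- fitELM(X, y, 10, seed = 5L)
  f2 <- fitELM(X, y, 10, seed = 5L)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_false(identical(predict(f1, X), predict(fitELM(X, y, 10, seed = 6L), X)))

  # interpolation regime: as many neurons as samples
  fBig <- fitELM(X, y, 25, seed = 1L)
  expect_lt(fBig@trainSummary[["RMSEC"]], 1e-6)

  # constant target is fit exactly at any width (pseudo-inverse solution)
  fConst <- fitELM(X, rep(7, 25), 3, seed = 2L)
  expect_lt(fConst@trainSummary[["RMSEC"]], 1e-8)

  # output weights match an independent SVD least-squares solution
  L <- f1@learned
  Xs <- sweep(sweep(X, 2, L$center, "-"), 2, L$scale, "/")
  H <- cbind(1 / (1 + exp(-(Xs %*% t(L$W) + matrix(L$b, 25, 10, byrow = TRUE)))), 1)
  sv <- svd(H)
  keep <- sv$d > max(sv$d) * 1e-12
  betaOracle <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  expect_equal(L$beta, as.numeric(betaOracle), tolerance = 1e-8)
})

test_that("ELM tuning searches the grid honestly", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40)
  y <- as.numeric(X %*% c(2, -1, 1)) + rnorm(40, 0, 0.2)
  folds <- makeFolds(40, 5, 4)
  single <- tuneELM(X, y, hRange = 5L, folds, seed = 1L)
  expect_identical(single$bestH, 5L)
  tuned <- tuneELM(X, y, hRange = c(1L, 5L, 10L, 20L), folds, seed = 1L)
  expect_lte(tuned$cvRmse[which(c(1L, 5L, 10L, 20L) == tuned$bestH)],
             tuned$cvRmse[1])
})

test_that("LSSVM satisfies its KKT system and interpolates at high gamma", {
  # 2-point fixture against the exact 3x3 solve
  X <- matrix(c(0, 1), 2, 1)
  y <- c(0, 1)
  f <- fitLSSVM(X, y, gamma = 1e8, sigma2 = 1, scaleInputs = FALSE)
  expect_lt(abs(predict(f, matrix(0)) - 0), 1e-3)
  expect_lt(abs(predict(f, matrix(1)) - 1), 1e-3)

  # constant target: alpha = 0, b = c solves the system
  fc <- fitLSSVM(X, c(3, 3), gamma = 10, sigma2 = 1, scaleInputs = FALSE)
  expect_equal(predict(fc, matrix(c(0, 0.5, 1))), rep(3, 3), tolerance = 1e-6)

  # KKT residual of the assembled system at the returned solution
  set.seed(5)
  Xr <- matrix(rnorm(20 * 3), 20)
  yr <- as.numeric(Xr %*% c(1, 1, -1)) + rnorm(20, 0, 0.1)
  fr <- fitLSSVM(Xr, yr, gamma = 50, sigma2 = 5)
  L <- fr@learned
  K <- exp(-as.matrix(stats::dist(L$Xs))^2 / fr@hyperparams$sigma2)
  A <- rbind(c(0, rep(1, 20)), cbind(rep(1, 20), K + diag(20) / 50))
  resid <- A %*% c(L$b, L$alpha) - c(0, yr)
  expect_lt(sqrt(sum(resid^2)), 1e-8 * sqrt(sum(yr^2)))

  # with standardisation on, predictions ignore a constant spectral offset
  shift <- Xr + 100
  frShift <- fitLSSVM(shift, yr, gamma = 50, sigma2 = 5)
  expect_equal(predict(frShift, shift), predict(fr, Xr), tolerance = 1e-8)
})

test_that("PSO follows its update rule and minimises the sphere", {
  # degenerate dynamics: no attraction, constant inertia -> linear motion
  seen <- new.env()
  seen$pos <- NULL
  obj <- function(x) {
    seen$pos <- rbind(seen$pos, x)
    sum(x^2)
  }
  cfg <- psoConfig(nParticles = 1L, nIter = 4L, w0 = 1, c1 = 0, c2 = 0,
                   bounds = rbind(c(-1e6, 1e6), c(-1e6, 1e6)), seed = 2L,
                   wEnd = 1)
  psoMinimize(obj, cfg)
  steps <- diff(seen$pos)
  expect_equal(steps[2, ], steps[1, ], tolerance = 1e-12)
  expect_equal(steps[3, ], steps[1, ], tolerance = 1e-12)

  # sphere benchmark with the study's swarm settings
  sph <- psoMinimize(function(x) sum(x^2),
                     psoConfig(bounds = rbind(c(-5, 5), c(-5, 5)), seed = 3L))
  expect_lte(sph$bestValue, 1e-3)
  expect_true(all(diff(sph$history) <= 0))
  expect_lte(sph$history[length(sph$history)], sph$history[1])

  # non-finite objective values are survivable
  nf <- psoMinimize(function(x) if (x[1] < 0) NaN else sum(x^2),
                    psoConfig(nParticles = 10L, nIter = 20L,
                              bounds = rbind(c(-5, 5)), seed = 4L))
  expect_true(is.finite(nf$bestValue))
})

test_that("PSO-tuned LSSVM improves on the search-box centre", {
  ds <- makeDataset(smallHsiConfig(seed = 9L, nSamples = 40L))
  X <- intensities(ds)[, seq(1, 60, by = 4)]
  y <- ssc(ds)
  folds <- makeFolds(40, 4, 9)
  cfg <- psoConfig(nParticles = 8L, nIter = 15L,
                   bounds = rbind(c(-2, 10), c(-2, 10)), seed = 9L)
  fit <- fitPsoLssvm(X, y, cfg, folds)
  expect_s4_class(fit, "FitResult")
  cvAt <- function(lg, ls) {
    sse <- 0
    for (te in folds) {
      tr <- setdiff(seq_len(40), te)
      f <- fitLSSVM(X[tr, , drop = FALSE], y[tr], 10^lg, 10^ls)
      sse <- sse + sum((predict(f, X[te, , drop = FALSE]) - y[te])^2)
    }
    sqrt(sse / 40)
  }
  expect_lte(fit@hyperparams$pso$bestValue, cvAt(4, 4)) # box centre

  # collapsed bounds return that point's fit
  point <- psoConfig(nParticles = 3L, nIter = 2L,
                     bounds = rbind(c(2, 2), c(1, 1)), seed = 1L)
  fp <- fitPsoLssvm(X, y, point, folds)
  expect_equal(fp@hyperparams$gamma, 100)
  expect_equal(fp@hyperparams$sigma2, 10)
})

test_that("train summaries are reproduced by predicting the training inputs", {
  set.seed(11)
  X <- matrix(rnorm(30 * 5), 30)
  y <- as.numeric(X %*% rnorm(5)) + rnorm(30, 0, 0.3)
  fits <- list(
    fitPLSR(X, y, 3),
    fitELM(X, y, 12, seed = 3L),
    fitLSSVM(X, y, gamma = 20, sigma2 = 10)
  )
  for (f in fits) {
    pred <- predict(f, X)
    expect_equal(rmse(y, pred), f@trainSummary[["RMSEC"]], tolerance = 1e-8)
    expect_equal(rSquared(y, pred), f@trainSummary[["R2c"]], tolerance = 1e-8)
    expect_lte(f@trainSummary[["R2c"]], 1)
  }
})
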
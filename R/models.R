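trainSummaryOf <- function(y, pred) {
  # a constant calibration target has no defined R2 but a valid RMSE
  r2 <- if (stats::var(y) > 0) rSquared(y, pred) else NA_real_
  c(R2c = r2, RMSEC = rmse(y, pred))
}

#' Fit a PLS1 regression model
#'
#' Deterministic NIPALS fit with exactly `lvs` latent variables; the learned
#' regression vector lives in the original band space (plus intercept), and
#' inputs are mean-centred only.
#'
#' @param X calibration sample-by-band matrix.
#' @param y calibration SSC vector (Brix).
#' @param lvs number of latent variables, `1 <= lvs <= min(n - 1, p)`.
#' @return A [FitResult-class] with `modelType = "PLSR"`.
#' @export
fitPLSR <- function(X, y, lvs) {
  X <- as.matrix(X)
  stopIfNot(stats::var(y) > 0, "y has zero variance")
  stopIfNot(isCount(lvs, 1L) && lvs <= min(nrow(X) - 1L, ncol(X)),
            "lvs must satisfy 1 <= lvs <= min(n - 1, p)")
  fit <- plsCoefficients(X, y, lvs)
  pred <- as.numeric(X %*% fit$coef + fit$intercept)
  new("FitResult", modelType = "PLSR",
      hyperparams = list(lvs = as.integer(lvs)),
      learned = list(coef = fit$coef, intercept = fit$intercept),
      trainSummary = trainSummaryOf(y, pred))
}

sigmoid <- function(t) 1 / (1 + exp(-t))

standardiseStats <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

applyStandardise <- function(X, st) {
  sweep(sweep(X, 2L, st$center, "-"), 2L, st$scale, "/")
}

#' Fit an extreme learning machine
#'
#' Single-hidden-layer network with logistic ("sig") activation: hidden
#' weights and biases are drawn i.i.d. uniform on `[-1, 1]` under `seed` and
#' never trained; the output layer (weights plus a bias term, so a constant
#' target is always fit exactly) is the Moore-Penrose least-squares solution
#' of `[H, 1] beta = y` (via [MASS::ginv()]). Inputs are z-scored by training
#' statistics by default to keep the sigmoid away from saturation.
#'
#' @param X calibration sample-by-band matrix.
#' @param y calibration SSC vector (Brix).
#' @param nHidden number of hidden neurons.
#' @param seed seed for the random hidden layer.
#' @param scaleInputs standardise inputs by training mean/sd.
#' @return A [FitResult-class] with `modelType = "ELM"`.
#' @export
fitELM <- function(X, y, nHidden, seed = 1L, scaleInputs = TRUE) {
  X <- as.matrix(X)
  stopIfNot(isCount(nHidden, 1L), "nHidden must be >= 1")
  p <- ncol(X)
  st <- if (scaleInputs) standardiseStats(X) else list(center = rep(0, p), scale = rep(1, p))
  Xs <- applyStandardise(X, st)
  hidden <- withSeed(seed, {
    list(W = matrix(stats::runif(nHidden * p, -1, 1), nHidden, p),
         b = stats::runif(nHidden, -1, 1))
  })
  H <- cbind(sigmoid(Xs %*% t(hidden$W) +
                       matrix(hidden$b, nrow(X), nHidden, byrow = TRUE)), 1)
  beta <- as.numeric(MASS::ginv(H) %*% y)
  pred <- as.numeric(H %*% beta)
  new("FitResult", modelType = "ELM",
      hyperparams = list(nHidden = as.integer(nHidden), seed = as.integer(seed)),
      learned = list(W = hidden$W, b = hidden$b, beta = beta,
                     center = st$center, scale = st$scale),
      trainSummary = trainSummaryOf(y, pred))
}

#' Tune the ELM hidden-layer size by cross-validation
#'
#' Grid search over `hRange` (default 1..100): for each size, k-fold
#' cross-validated RMSE with hidden weights redrawn per fold under derived
#' seeds, averaged over `nRepeats` independent hidden-layer draws (the network
#' is random, so a single draw per size is a noisy estimate whose argmin
#' over-selects interpolating sizes); the final model is refit on all
#' calibration data at the best size (smallest size on ties).
#'
#' @inheritParams fitELM
#' @param hRange candidate hidden-layer sizes.
#' @param folds list of test-index vectors, e.g. [makeFolds()].
#' @param nRepeats hidden-layer redraws averaged per candidate size.
#' @return List with `bestH`, `fit` (a [FitResult-class]) and `cvRmse`.
#' @export
tuneELM <- function(X, y, hRange = 1:100, folds, seed = 1L, scaleInputs = TRUE,
                    nRepeats = 3L) {
  X <- as.matrix(X)
  stopIfNot(length(hRange) >= 1L, "hRange must be non-empty")
  stopIfNot(isCount(nRepeats, 1L), "nRepeats must be >= 1")
  n <- nrow(X)
  cvRmse <- vapply(seq_along(hRange), function(hi) {
    h <- hRange[hi]
    reps <- vapply(seq_len(nRepeats), function(rep) {
      sse <- 0
      for (fi in seq_along(folds)) {
        te <- folds[[fi]]
        tr <- setdiff(seq_len(n), te)
        fit <- fitELM(X[tr, , drop = FALSE], y[tr], h,
                      seed = deriveSeed(seed, (hi * 7L + rep) * 1000L + fi),
                      scaleInputs = scaleInputs)
        pred <- predict(fit, X[te, , drop = FALSE])
        sse <- sse + sum((pred - y[te])^2)
      }
      sqrt(sse / n)
    }, 0)
    mean(reps)
  }, 0)
  bestH <- hRange[which.min(cvRmse)]
  list(bestH = as.integer(bestH),
       fit = fitELM(X, y, bestH, seed = seed, scaleInputs = scaleInputs),
       cvRmse = cvRmse)
}

rbfKernel <- function(A, B, sigma2) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-pmax(D2, 0) / sigma2)
}

#' Fit a least-squares support vector machine (RBF kernel)
#'
#' Solves the LS-SVM dual KKT system
#' `[[0, 1'], [1, K + I/gamma]] [b; alpha] = [0; y]` with
#' `K_ij = exp(-||x_i - x_j||^2 / sigma2)`; prediction is
#' `f(x) = sum_i alpha_i K(x, x_i) + b`. Inputs are standardised with training
#' statistics so the RBF width is comparable across bands.
#'
#' @param X calibration sample-by-band matrix.
#' @param y calibration SSC vector (Brix).
#' @param gamma regularisation parameter, `> 0`.
#' @param sigma2 RBF kernel width, `> 0`.
#' @param scaleInputs standardise inputs by training mean/sd.
#' @return A [FitResult-class] with `modelType = "LSSVM"`.
#' @export
fitLSSVM <- function(X, y, gamma, sigma2, scaleInputs = TRUE) {
  X <- as.matrix(X)
  stopIfNot(is.numeric(gamma) && gamma > 0, "gamma must be > 0")
  stopIfNot(is.numeric(sigma2) && sigma2 > 0, "sigma2 must be > 0")
  n <- nrow(X)
  p <- ncol(X)
  st <- if (scaleInputs) standardiseStats(X) else list(center = rep(0, p), scale = rep(1, p))
  Xs <- applyStandardise(X, st)
  K <- rbfKernel(Xs, Xs, sigma2)
  A <- rbind(c(0, rep(1, n)), cbind(rep(1, n), K + diag(n) / gamma))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop(sprintf(
      "LSSVM KKT system is numerically singular (rcond = %.3e); adjust gamma/sigma2",
      rcond(A)), call. = FALSE)
  })
  b <- sol[1]
  alpha <- sol[-1]
  pred <- as.numeric(K %*% alpha + b)
  new("FitResult", modelType = "LSSVM",
      hyperparams = list(gamma = gamma, sigma2 = sigma2),
      learned = list(alpha = alpha, b = b, Xs = Xs,
                     center = st$center, scale = st$scale),
      trainSummary = trainSummaryOf(y, pred))
}

#' Predict from a fitted model
#'
#' @param object a [FitResult-class].
#' @param newX matrix of spectra on the same band set the model was fitted on.
#' @param ... ignored.
#' @return Numeric vector of predicted SSC (Brix).
#' @export
setMethod("predict", "FitResult", function(object, newX, ...) {
  newX <- as.matrix(newX)
  L <- object@learned
  switch(object@modelType,
    PLSR = {
      stopIfNot(ncol(newX) == length(L$coef), "band count mismatch with fit")
      as.numeric(newX %*% L$coef + L$intercept)
    },
    ELM = {
      stopIfNot(ncol(newX) == ncol(L$W), "band count mismatch with fit")
      Xs <- applyStandardise(newX, list(center = L$center, scale = L$scale))
      H <- cbind(sigmoid(Xs %*% t(L$W) +
                           matrix(L$b, nrow(newX), length(L$b), byrow = TRUE)), 1)
      as.numeric(H %*% L$beta)
    },
    LSSVM = {
      stopIfNot(ncol(newX) == ncol(L$Xs), "band count mismatch with fit")
      Xs <- applyStandardise(newX, list(center = L$center, scale = L$scale))
      K <- rbfKernel(Xs, L$Xs, object@hyperparams$sigma2)
      as.numeric(K %*% L$alpha + L$b)
    }
  )
})

#' Particle swarm optimiser configuration
#'
#' @param nParticles swarm size.
#' @param nIter iterations.
#' @param w0 initial inertia weight; decays linearly to `wEnd`.
#' @param c1,c2 cognitive and social learning factors.
#' @param bounds 2-column matrix, one row per dimension: `(lo, hi)`.
#' @param seed RNG seed.
#' @param wEnd final inertia weight (set `wEnd = w0` for constant inertia).
#' @return A validated `PSOConfig` list.
#' @export
psoConfig <- function(nParticles = 20L, nIter = 100L, w0 = 0.90,
                      c1 = 2, c2 = 2, bounds, seed = 1L, wEnd = 0.4) {
  stopIfNot(isCount(nParticles, 1L) && isCount(nIter, 1L),
            "nParticles and nIter must be counts >= 1")
  stopIfNot(c1 >= 0 && c2 >= 0, "c1 and c2 must be >= 0")
  bounds <- as.matrix(bounds)
  stopIfNot(ncol(bounds) == 2L && all(bounds[, 1] <= bounds[, 2]),
            "bounds must be a (lo, hi) matrix with lo <= hi per dimension")
  structure(list(nParticles = as.integer(nParticles), nIter = as.integer(nIter),
                 w0 = w0, c1 = c1, c2 = c2, bounds = bounds,
                 seed = as.integer(seed), wEnd = wEnd),
            class = "PSOConfig")
}

#' Particle swarm minimisation
#'
#' Standard global-best PSO on a box: per particle and dimension,
#' `V <- w V + c1 r1 (Pbest - X) + c2 r2 (Gbest - X)`, `X <- X + V`, with
#' `r1, r2 ~ U(0, 1)` drawn per particle per dimension, inertia decaying
#' linearly from `w0` to `wEnd`, and positions clamped to the bounds. An
#' objective returning a non-finite value scores as `+Inf` for that particle.
#'
#' @param objective function mapping a position vector to a scalar.
#' @param cfg a [psoConfig()].
#' @return List with `bestPosition`, `bestValue`, and `history` (best value
#'   per iteration; non-increasing).
#' @export
psoMinimize <- function(objective, cfg) {
  stopifnot(inherits(cfg, "PSOConfig"))
  d <- nrow(cfg$bounds)
  lo <- cfg$bounds[, 1]
  hi <- cfg$bounds[, 2]
  span <- hi - lo
  evalSafe <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  }
  withSeed(cfg$seed, {
    Xp <- matrix(stats::runif(cfg$nParticles * d), cfg$nParticles, d)
    Xp <- sweep(sweep(Xp, 2L, span, "*"), 2L, lo, "+")
    V <- matrix(stats::runif(cfg$nParticles * d, -1, 1), cfg$nParticles, d) *
      matrix(span, cfg$nParticles, d, byrow = TRUE) * 0.1
    fit <- apply(Xp, 1L, evalSafe)
    Pbest <- Xp
    PbestVal <- fit
    gi <- which.min(fit)
    Gbest <- Xp[gi, ]
    GbestVal <- fit[gi]
    history <- numeric(cfg$nIter)
    for (it in seq_len(cfg$nIter)) {
      w <- if (cfg$nIter == 1L) cfg$w0 else
        cfg$w0 + (cfg$wEnd - cfg$w0) * (it - 1) / (cfg$nIter - 1)
      r1 <- matrix(stats::runif(cfg$nParticles * d), cfg$nParticles, d)
      r2 <- matrix(stats::runif(cfg$nParticles * d), cfg$nParticles, d)
      V <- w * V + cfg$c1 * r1 * (Pbest - Xp) +
        cfg$c2 * r2 * (matrix(Gbest, cfg$nParticles, d, byrow = TRUE) - Xp)
      Xp <- Xp + V
      Xp <- pmin(pmax(Xp, matrix(lo, cfg$nParticles, d, byrow = TRUE)),
                 matrix(hi, cfg$nParticles, d, byrow = TRUE))
      fit <- apply(Xp, 1L, evalSafe)
      improved <- fit < PbestVal
      Pbest[improved, ] <- Xp[improved, , drop = FALSE]
      PbestVal[improved] <- fit[improved]
      gi <- which.min(PbestVal)
      if (PbestVal[gi] < GbestVal) {
        GbestVal <- PbestVal[gi]
        Gbest <- Pbest[gi, ]
      }
      history[it] <- GbestVal
    }
    list(bestPosition = Gbest, bestValue = GbestVal, history = history)
  })
}

#' Fit an LS-SVM with PSO-tuned hyperparameters
#'
#' Particle swarm search over `(log10 gamma, log10 sigma2)` minimising the
#' k-fold cross-validated RMSE of [fitLSSVM()]; the final model is refit on all
#' calibration data at the optimum. Defaults follow standard practice for this
#' optimiser: 20 particles, 100 iterations, initial inertia 0.90 decaying to
#' 0.4, `c1 = c2 = 2`, and a log-scale box of `[1e-2, 1e10]` per dimension
#' (LS-SVM regularisation optima on spectra span many orders of magnitude).
#'
#' @inheritParams fitLSSVM
#' @param cfg a [psoConfig()]; `NULL` uses the defaults above.
#' @param folds list of test-index vectors, e.g. [makeFolds()].
#' @return A [FitResult-class] with `modelType = "LSSVM"`; the PSO search
#'   record is attached as `hyperparams$pso`.
#' @export
fitPsoLssvm <- function(X, y, cfg = NULL, folds, scaleInputs = TRUE) {
  X <- as.matrix(X)
  if (is.null(cfg)) {
    cfg <- psoConfig(bounds = rbind(c(-2, 10), c(-2, 10)))
  }
  n <- nrow(X)
  objective <- function(pos) {
    gamma <- 10^pos[1]
    sigma2 <- 10^pos[2]
    sse <- 0
    for (te in folds) {
      tr <- setdiff(seq_len(n), te)
      fit <- tryCatch(
        fitLSSVM(X[tr, , drop = FALSE], y[tr], gamma, sigma2, scaleInputs),
        error = function(e) NULL
      )
      if (is.null(fit)) return(Inf)
      pred <- predict(fit, X[te, , drop = FALSE])
      sse <- sse + sum((pred - y[te])^2)
    }
    sqrt(sse / n)
  }
  opt <- psoMinimize(objective, cfg)
  fit <- fitLSSVM(X, y, 10^opt$bestPosition[1], 10^opt$bestPosition[2],
                  scaleInputs)
  fit@hyperparams$pso <- list(cfg = cfg, bestValue = opt$bestValue,
                              history = opt$history)
  fit
}
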
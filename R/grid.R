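#' Compare pre-processing methods through PLSR
#'
#' For each requested operator: pre-process, Kennard-Stone split, choose the
#' latent-variable count by k-fold cross-validation on the calibration set,
#' fit PLSR, and evaluate. The row with the highest RPD is flagged.
#'
#' @param ds a [SpectralDataset-class].
#' @param methods operators to compare.
#' @param ratio calibration fraction for the split.
#' @param maxLv latent-variable search cap.
#' @param kFolds cross-validation folds.
#' @param masterSeed seed for fold construction.
#' @return `data.frame` of [evaluateModel()] rows plus `lvs` and `best`.
#' @export
runPrepComparison <- function(ds,
                              methods = c("raw", "SNV", "DT", "SG", "GWS", "BS", "ES"),
                              ratio = 2 / 3, maxLv = 20L, kFolds = 5L,
                              masterSeed = 1L) {
  stopifnot(is(ds, "SpectralDataset"))
  rows <- lapply(methods, function(m) {
    pp <- applyPreprocess(ds, preprocessSpec(m))
    sp <- ksSplit(pp, ratio)
    folds <- makeFolds(nSamples(sp$train), kFolds, deriveSeed(masterSeed, 0L))
    Xtr <- intensities(sp$train)
    lv <- selectLvs(Xtr, ssc(sp$train), min(maxLv, nrow(Xtr) - 1L, ncol(Xtr)),
                    folds)
    fit <- fitPLSR(Xtr, ssc(sp$train), lv)
    cbind(evaluateModel(fit, sp$train, sp$test, NULL, pipeline = m),
          lvs = lv)
  })
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.max(out$RPD)
  out
}

#' The paper-style selector set for one modality
#'
#' The five primary selectors with their modality-specific latent-variable
#' caps and fold counts (Boss lv 17/20 folds 5; CARS lv 18 folds 5; IVSO lv
#' 14/16 folds 9/7; IVISSA lv 19/17 folds 10; MASS lv 13/14 folds 5), plus the
#' three secondary Boss cascades (CARS-Boss, MASS-Boss, IVISSA-Boss).
#'
#' @param modality `"HSI"` or `"FSI"`.
#' @param nSampling sub-models per iteration (1000 reproduces the study-scale
#'   runs; smaller values keep desk-scale experiments fast).
#' @param carsRuns Monte-Carlo runs for CARS (study scale: 100).
#' @param seed base selector seed.
#' @return Named list whose elements are either a [selectorParams()] or a
#'   `list(first =, then =)` cascade pair.
#' @export
defaultSelectorGrid <- function(modality = c("HSI", "FSI"), nSampling = 200L,
                                carsRuns = 100L, seed = 1L) {
  modality <- match.arg(modality)
  hsi <- modality == "HSI"
  boss <- selectorParams("Boss", maxLv = if (hsi) 17L else 20L, kFolds = 5L,
                         nSampling = nSampling, seed = seed)
  cars <- selectorParams("CARS", maxLv = 18L, kFolds = 5L,
                         nSampling = carsRuns, seed = seed)
  ivso <- selectorParams("IVSO", maxLv = if (hsi) 14L else 16L,
                         kFolds = if (hsi) 9L else 7L,
                         nSampling = nSampling, seed = seed)
  ivissa <- selectorParams("IVISSA", maxLv = if (hsi) 19L else 17L,
                           kFolds = 10L, nSampling = nSampling, seed = seed)
  mass <- selectorParams("MASS", maxLv = if (hsi) 13L else 14L, kFolds = 5L,
                         nSampling = nSampling, seed = seed)
  bossSecond <- function(s) selectorParams("Boss", maxLv = if (hsi) 17L else 20L,
                                           kFolds = 5L, nSampling = nSampling,
                                           seed = deriveSeed(seed, s))
  list(
    Boss = boss, CARS = cars, IVSO = ivso, IVISSA = ivissa, MASS = mass,
    `CARS-Boss` = list(first = cars, then = bossSecond(21L)),
    `MASS-Boss` = list(first = mass, then = bossSecond(22L)),
    `IVISSA-Boss` = list(first = ivissa, then = bossSecond(23L))
  )
}

runOneSelector <- function(X, y, sel) {
  if (inherits(sel, "SelectorParams")) {
    runSelector(X, y, sel)
  } else {
    runCascade(X, y, sel$first, sel$then)
  }
}

#' Run the selector-by-model benchmark grid
#'
#' Reproduces the experimental design of the study: one pre-processing step,
#' one shared Kennard-Stone split, every selector run once on the calibration
#' set, and every model fitted on every selection. All cells share the split
#' and fold structure (seeded from `masterSeed`); per-cell randomness uses
#' seeds derived from `masterSeed` and the cell name, so cells are independent
#' yet reproducible. Failed cells are reported as rows with `failed = TRUE`
#' rather than dropped.
#'
#' @param ds a [SpectralDataset-class].
#' @param prep a [preprocessSpec()] applied before splitting.
#' @param selectors named list of [selectorParams()] or `list(first =, then =)`
#'   cascade pairs, e.g. [defaultSelectorGrid()].
#' @param models character subset of `c("PLSR", "ELM", "PSO-LSSVM")`.
#' @param ratio calibration fraction.
#' @param kFolds folds for model hyperparameter selection.
#' @param masterSeed master seed.
#' @param elmRange ELM hidden-size grid.
#' @param psoCfg PSO configuration for LS-SVM tuning; `NULL` uses
#'   [fitPsoLssvm()] defaults.
#' @return List with `results` (one row per cell) and `best` (argmax-RPD row
#'   per model).
#' @export
runGrid <- function(ds, prep, selectors, models = c("PLSR", "ELM", "PSO-LSSVM"),
                    ratio = 2 / 3, kFolds = 5L, masterSeed = 1L,
                    elmRange = 1:100, psoCfg = NULL) {
  stopifnot(is(ds, "SpectralDataset"))
  stopIfNot(length(selectors) >= 1L && length(models) >= 1L,
            "need at least one selector and one model")
  pp <- applyPreprocess(ds, prep)
  sp <- ksSplit(pp, ratio)
  Xtr <- intensities(sp$train)
  yTr <- ssc(sp$train)
  folds <- makeFolds(nrow(Xtr), kFolds, deriveSeed(masterSeed, 0L))

  selNames <- names(selectors)
  if (is.null(selNames)) selNames <- paste0("selector", seq_along(selectors))
  rows <- list()
  for (si in seq_along(selectors)) {
    selResult <- tryCatch(runOneSelector(Xtr, yTr, selectors[[si]]),
                          error = function(e) e)
    for (m in models) {
      cellName <- paste(selNames[si], m, sep = "/")
      cellSeed <- deriveSeed(masterSeed, si * 100L + match(m, models))
      row <- tryCatch({
        if (inherits(selResult, "error")) stop(conditionMessage(selResult))
        bands <- selectedBands(selResult)
        Xsel <- Xtr[, bands, drop = FALSE]
        fit <- switch(m,
          PLSR = {
            lv <- selectLvs(Xsel, yTr, min(20L, length(bands), nrow(Xsel) - 1L),
                            folds)
            fitPLSR(Xsel, yTr, lv)
          },
          ELM = tuneELM(Xsel, yTr, elmRange, folds, seed = cellSeed)$fit,
          `PSO-LSSVM` = {
            cfg <- if (is.null(psoCfg)) {
              psoConfig(bounds = rbind(c(-2, 10), c(-2, 10)), seed = cellSeed)
            } else {
              psoConfig(psoCfg$nParticles, psoCfg$nIter, psoCfg$w0, psoCfg$c1,
                        psoCfg$c2, psoCfg$bounds, seed = cellSeed,
                        wEnd = psoCfg$wEnd)
            }
            fitPsoLssvm(Xsel, yTr, cfg, folds)
          },
          stop(sprintf("unknown model: %s", m))
        )
        r <- evaluateModel(fit, sp$train, sp$test, selResult,
                           pipeline = selNames[si])
        r$failed <- FALSE
        r$error <- NA_character_
        r
      }, error = function(e) {
        data.frame(pipeline = selNames[si], model = m, nFeatures = NA_integer_,
                   R2c = NA_real_, RMSEC = NA_real_, R2p = NA_real_,
                   RMSEP = NA_real_, RPD = NA_real_, grade = NA_character_,
                   failed = TRUE, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[cellName]] <- row
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ok <- results[!results$failed & is.finite(results$RPD), , drop = FALSE]
  best <- do.call(rbind, lapply(split(ok, ok$model), function(g)
    g[which.max(g$RPD), , drop = FALSE]))
  rownames(best) <- NULL
  list(results = results, best = best, split = sp$split)
}
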
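#' Default hyperparameter search space
#'
#' Bounds for the tunable hyperparameters of the protocol: learning rate,
#' weight decay, dropout, warmup epochs, the two hidden widths, label
#' smoothing, triplet margin, KL weight beta and batch-removal weight gamma
#' (the last three only where the grid cell uses them). Each entry is a
#' list with `min`/`max` and optional flags `log` (sample on the log scale)
#' and `integer`.
#'
#' @return named list of parameter ranges.
#' @export
defaultSearchSpace <- function() {
  list(
    learningRate = list(min = 1e-4, max = 1e-2, log = TRUE),
    weightDecay = list(min = 1e-8, max = 1e-3, log = TRUE),
    dropout = list(min = 0, max = 0.5),
    warmupEpochs = list(min = 5, max = 50, integer = TRUE),
    layer1 = list(min = 32, max = 128, integer = TRUE),
    layer2 = list(min = 32, max = 128, integer = TRUE),
    labelSmoothing = list(min = 0, max = 0.2),
    margin = list(min = 0.1, max = 5, log = TRUE),
    beta = list(min = 1e-3, max = 1, log = TRUE),
    gamma = list(min = 1e-2, max = 10, log = TRUE))
}

sampleFromRange <- function(range) {
  if (isTRUE(range$log)) {
    v <- exp(runif(1, log(range$min), log(range$max)))
  } else {
    v <- runif(1, range$min, range$max)
  }
  if (isTRUE(range$integer)) v <- as.integer(round(v)) else v
}

#' Hyperparameter search for one grid cell
#'
#' Evaluates `budget` hyperparameter combinations of one backbone x removal
#' cell by seeded random search (the strategy is declared in the result),
#' scoring each by the mean *validation* MCC of a repetitive holdout run.
#' Test MCC is recorded but never used for selection.
#'
#' @param ds an [OmicsSet-class].
#' @param backbone,removal the grid cell to tune.
#' @param space search space as in [defaultSearchSpace()]; entries
#'   irrelevant to the cell are ignored.
#' @param budget number of configurations to evaluate (>= 1).
#' @param baseConfig a [TrainConfig()] supplying the non-searched protocol
#'   settings (scenario, epoch caps, batch size).
#' @param nIterations holdout iterations per configuration.
#' @param seed integer seed.
#' @param ... forwarded to [runRepetitiveHoldout()].
#' @return list with `best` (the winning [TrialResult-class]), `trials`
#'   (a data.frame of evaluated configurations and their mean MCCs) and
#'   `strategy` (`"seeded random search"`).
#' @export
hyperparameterSearch <- function(ds, backbone, removal, space = defaultSearchSpace(),
                                 budget = 20, baseConfig = TrainConfig(),
                                 nIterations = 3, seed = 1, ...) {
  if (budget < 1) stopf("budget must be >= 1")
  relevant <- c("learningRate", "weightDecay", "dropout", "warmupEpochs",
                "layer1", "layer2", "labelSmoothing")
  if (removal %in% c("invTriplet", "revTriplet")) relevant <- c(relevant, "margin")
  if (backbone == "VAE") relevant <- c(relevant, "beta")
  if (removal != "none") relevant <- c(relevant, "gamma")

  trials <- list()
  results <- list()
  for (i in seq_len(budget)) {
    draw <- withSeed(childSeed(seed, 300L + i), {
      lapply(space[intersect(relevant, names(space))], sampleFromRange)
    })
    specArgs <- draw[intersect(names(draw),
                               c("layer1", "layer2", "dropout", "labelSmoothing",
                                 "margin", "beta", "gamma"))]
    specArgs$backbone <- backbone
    specArgs$removal <- removal
    spec <- do.call(ModelSpec, specArgs)
    cfg <- baseConfig
    if (!is.null(draw$learningRate)) cfg@learningRate <- draw$learningRate
    if (!is.null(draw$weightDecay)) cfg@weightDecay <- draw$weightDecay
    if (!is.null(draw$warmupEpochs)) cfg@warmupEpochs <- as.integer(draw$warmupEpochs)
    cfg@seed <- childSeed(seed, 400L + i)
    res <- runRepetitiveHoldout(ds, spec, cfg, nIterations = nIterations,
                                seed = childSeed(seed, 500L + i), ...)
    results[[i]] <- res
    trials[[i]] <- data.frame(trial = i, as.data.frame(draw),
                              meanValidMCC = res@meanValidMCC,
                              meanTestMCC = res@meanTestMCC)
  }
  trialTab <- do.call(rbind, lapply(trials, function(d) {
    # pad columns so rbind works across cells with different search spaces
    d
  }))
  bestIdx <- which.max(vapply(results, function(r) r@meanValidMCC, 1))
  list(best = results[[bestIdx]], trials = trialTab, strategy = "seeded random search")
}
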
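#' Training protocol configuration
#'
#' Defaults mirror the study protocol: minibatch size 32, up to 1000
#' epochs after warmup, early stopping when validation MCC has not improved
#' for 100 consecutive epochs. Two scenarios exist: `"frozen"` trains only
#' the condition classifier after warmup (the autoencoder is frozen), while
#' `"alternating"` alternates one full unsupervised epoch (reconstruction,
#' KL, batch-removal terms on all samples) with one full supervised epoch
#' whose gradients flow through the encoder.
#'
#' @param scenario `"frozen"` or `"alternating"`.
#' @param warmupEpochs unsupervised warmup epochs on the whole dataset.
#' @param maxEpochs maximum post-warmup epochs.
#' @param patience early-stopping patience on validation MCC.
#' @param batchSize minibatch size.
#' @param learningRate,weightDecay Adam step size and L2 weight decay.
#' @param seed integer seed governing all training randomness.
#' @return a [TrainConfig-class].
#' @export
TrainConfig <- function(scenario = c("alternating", "frozen"), warmupEpochs = 50,
                        maxEpochs = 1000, patience = 100, batchSize = 32,
                        learningRate = 1e-3, weightDecay = 1e-5, seed = 1) {
  scenario <- match.arg(scenario)
  methods::new("TrainConfig", scenario = scenario,
               warmupEpochs = as.integer(warmupEpochs), maxEpochs = as.integer(maxEpochs),
               patience = as.integer(patience), batchSize = as.integer(batchSize),
               learningRate = as.numeric(learningRate), weightDecay = as.numeric(weightDecay),
               seed = as.integer(seed))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: %s scenario, warmup %d, max %d (patience %d), batch %d\n",
              object@scenario, object@warmupEpochs, object@maxEpochs,
              object@patience, object@batchSize))
  cat(sprintf("  lr=%.3g weightDecay=%.3g seed=%d\n",
              object@learningRate, object@weightDecay, object@seed))
})

minibatchIndices <- function(n, batchSize) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batchSize))
}

# One unsupervised epoch over the supplied rows; returns updated params/opt
# plus mean losses. For the adversarial removals the batch head receives
# extra head-only updates per minibatch: only against a near-optimal
# discriminator does holding the cross-entropy at the random plateau force
# genuine batch mixing rather than a lagging pursuit.
unsupEpoch <- function(model, X, idx, cfg, opt, headSteps = 3L) {
  comp <- c(rec = 0, batchTerm = 0, kl = 0)
  nb <- 0
  adversarial <- model@spec@removal %in% c("DANN", "NormAE") && model@spec@gamma > 0
  for (mb in minibatchIndices(nrow(X), cfg@batchSize)) {
    if (length(mb) < 2) next
    if (adversarial) {
      for (s in seq_len(headSteps)) {
        hg <- headGrads(model, X[mb, , drop = FALSE], idx[mb])
        step <- adamStep(model@params, hg$grads, opt, cfg@learningRate, cfg@weightDecay)
        model@params <- step$params
        opt <- step$state
      }
    }
    res <- computeGrads(model, X[mb, , drop = FALSE], idx[mb], pass = "unsup")
    step <- adamStep(model@params, res$grads, opt, cfg@learningRate, cfg@weightDecay)
    model@params <- step$params
    opt <- step$state
    comp <- comp + c(res$losses$rec, res$losses$batchTerm, res$losses$kl)
    nb <- nb + 1
  }
  list(model = model, opt = opt, losses = comp / max(nb, 1))
}

# One supervised epoch with class-weighted resampling of the labeled rows.
supEpoch <- function(model, X, idx, y, rows, weights, cfg, opt, flowEncoder) {
  drawn <- sample(rows, size = length(rows), replace = TRUE, prob = weights)
  ce <- 0
  nb <- 0
  for (mb in split(drawn, ceiling(seq_along(drawn) / cfg@batchSize))) {
    res <- computeGrads(model, X[mb, , drop = FALSE], idx[mb], y = y[mb],
                        pass = "sup", flowEncoder = flowEncoder)
    step <- adamStep(model@params, res$grads, opt, cfg@learningRate, cfg@weightDecay)
    model@params <- step$params
    opt <- step$state
    ce <- ce + res$losses$labelCE
    nb <- nb + 1
  }
  list(model = model, opt = opt, labelCE = ce / max(nb, 1))
}

#' Unsupervised warmup on the whole dataset
#'
#' Trains only the unsupervised components — reconstruction (plus KL for
#' the VAE backbone) and the batch-removal term — on *all* samples,
#' including validation/test batches and QC samples. Class labels are never
#' read; the condition classifier's parameters are untouched.
#' `warmupEpochs = 0` returns the model unchanged.
#'
#' @param model a [DebatchModel-class].
#' @param dsAll the full [OmicsSet-class] (all splits and QCs).
#' @param cfg a [TrainConfig()].
#' @return the warmed-up [DebatchModel-class].
#' @export
warmup <- function(model, dsAll, cfg) {
  validObject(cfg)
  if (cfg@warmupEpochs == 0) return(model)
  X <- intensities(dsAll)
  idx <- batchIndex(model, as.character(batchLabels(dsAll)), nrow(X))
  withSeed(childSeed(cfg@seed, 1L), {
    opt <- adamInit()
    for (e in seq_len(cfg@warmupEpochs)) {
      res <- unsupEpoch(model, X, idx, cfg, opt)
      model <- res$model
      opt <- res$opt
    }
  })
  model
}

#' Early-stopping decision on a validation-MCC history
#'
#' Training halts after epoch `e` when the best validation MCC so far lies
#' `patience` or more epochs in the past, or when `maxEpochs` is reached.
#' Ties keep the earlier epoch (less overfit parameters are preferred).
#'
#' @param mcc numeric vector of per-epoch validation MCCs (possibly longer
#'   than what would actually be run; entries beyond the stopping point are
#'   ignored).
#' @param patience consecutive non-improving epochs tolerated.
#' @param maxEpochs hard epoch cap.
#' @return list with `stopEpoch` (last epoch executed) and `bestEpoch`
#'   (epoch whose parameters are kept).
#' @export
earlyStopping <- function(mcc, patience, maxEpochs = length(mcc)) {
  horizon <- min(length(mcc), maxEpochs)
  stopEpoch <- horizon
  for (e in seq_len(horizon)) {
    best <- which.max(mcc[seq_len(e)])
    if (e - best >= patience) {
      stopEpoch <- e
      break
    }
  }
  list(stopEpoch = stopEpoch, bestEpoch = which.max(mcc[seq_len(stopEpoch)]))
}

#' Train a warmed-up model under one holdout split
#'
#' Scenario `"frozen"` updates only the condition classifier on the
#' training batches; `"alternating"` alternates a full unsupervised epoch
#' on all samples with a supervised epoch whose gradients flow through the
#' encoder. Supervised minibatches are drawn with inverse-class-frequency
#' weighted sampling (see [classWeights()]) from non-QC training samples.
#' After every epoch the validation MCC is computed from the model's
#' predictions on the validation batches; early stopping keeps the
#' parameters of the best-validation-MCC epoch (earlier epoch on ties).
#' Test labels are never read here — test predictions and scores belong to
#' the evaluation step.
#'
#' @param model a warmed-up [DebatchModel-class].
#' @param split a [SplitPlan-class].
#' @param ds the full [OmicsSet-class].
#' @param cfg a [TrainConfig()].
#' @return list with `model` (best-epoch parameters), `history` (per-epoch
#'   loss components and validation MCC), `bestEpoch`, `stopEpoch`.
#' @export
trainScenario <- function(model, split, ds, cfg) {
  validObject(cfg)
  X <- intensities(ds)
  bidx <- batchIndex(model, as.character(batchLabels(ds)), nrow(X))
  assign <- splitAssignment(ds, split)
  cls <- classLabels(ds)
  y <- classIndexVector(model, as.character(cls), nrow(X))

  trainRows <- which(assign == "train" & !isQC(ds) & !is.na(y))
  validRows <- which(assign == "valid" & !isQC(ds) & !is.na(y))
  if (!length(trainRows)) stopf("no labeled non-QC samples in the training split")
  if (length(unique(y[validRows])) < 2) {
    stopf("validation split [%s] has a single class: MCC undefined",
          paste(split@validBatches, collapse = ", "))
  }
  weights <- classWeights(y[trainRows])

  history <- data.frame(epoch = integer(), rec = numeric(), batchTerm = numeric(),
                        kl = numeric(), labelCE = numeric(), validMCC = numeric())
  bestParams <- model@params
  bestMCC <- -Inf
  mccTrace <- numeric(0)

  withSeed(childSeed(cfg@seed, 2L), {
    opt <- adamInit()
    for (e in seq_len(cfg@maxEpochs)) {
      losses <- c(rec = NA_real_, batchTerm = NA_real_, kl = NA_real_)
      if (cfg@scenario == "alternating") {
        resU <- unsupEpoch(model, X, bidx, cfg, opt)
        model <- resU$model
        opt <- resU$opt
        losses <- resU$losses
      }
      resS <- supEpoch(model, X, bidx, y, trainRows, weights, cfg, opt,
                       flowEncoder = (cfg@scenario == "alternating"))
      model <- resS$model
      opt <- resS$opt

      predV <- predictClasses(model, X[validRows, , drop = FALSE])
      mccV <- matthewsCC(model@classLevels[y[validRows]], as.character(predV))
      mccTrace[e] <- mccV
      history[e, ] <- list(e, losses[["rec"]], losses[["batchTerm"]], losses[["kl"]],
                           resS$labelCE, mccV)
      if (mccV > bestMCC) {
        bestMCC <- mccV
        bestParams <- model@params
      }
      if (e - which.max(mccTrace) >= cfg@patience) break
    }
  })
  model@params <- bestParams
  es <- earlyStopping(mccTrace, cfg@patience, cfg@maxEpochs)
  list(model = model, history = history, bestEpoch = es$bestEpoch,
       stopEpoch = length(mccTrace))
}

#' Repetitive holdout evaluation of one model specification
#'
#' For each iteration: draw a fresh batch-level split, build a fresh model
#' (seed offset by the iteration), warm it up on the whole dataset, train
#' under the configured scenario, then score the bottleneck embedding of
#' the validation and test batches with the full metrics panel, using the
#' condition classifier's predictions for MCC. Deterministic given `seed`.
#'
#' @param ds an [OmicsSet-class] with at least 3 batches.
#' @param spec a [ModelSpec()].
#' @param cfg a [TrainConfig()].
#' @param nIterations number of holdout iterations.
#' @param seed integer seed (drives splits, initialization and training).
#' @param validFraction,testFraction batch fractions for [makeHoldoutSplits()].
#' @param splits optionally, a pre-built list of [SplitPlan-class] to reuse
#'   (e.g. to share splits across benchmark methods).
#' @param k probe neighbour count for the metrics panel.
#' @return a [TrialResult-class].
#' @export
runRepetitiveHoldout <- function(ds, spec, cfg, nIterations = 5, seed = 1,
                                 validFraction = 0.2, testFraction = 0.2,
                                 splits = NULL, k = 20) {
  if (is.null(splits)) {
    splits <- makeHoldoutSplits(ds, nIterations, validFraction, testFraction, seed)
  }
  batch <- batchLabels(ds)
  clsLevels <- levels(factor(classLabels(ds)))
  validReports <- list()
  testReports <- list()
  name <- modelName(spec)
  for (it in seq_along(splits)) {
    model <- buildModel(spec, nrow(ds), nlevels(batch), length(clsLevels),
                        seed = childSeed(seed, 100L + it),
                        batchLevels = levels(batch), classLevels = clsLevels)
    cfgIt <- cfg
    cfgIt@seed <- childSeed(cfg@seed, 200L + it)
    model <- warmup(model, ds, cfgIt)
    fit <- trainScenario(model, splits[[it]], ds, cfgIt)
    model <- fit$model

    Z <- encode(model, intensities(ds))$z
    assign <- splitAssignment(ds, splits[[it]])
    for (sp in c("valid", "test")) {
      rows <- which(assign == sp)
      dsS <- ds[, rows]
      yPred <- predictClasses(model, intensities(ds)[rows, , drop = FALSE])
      rep_ <- evaluateRepresentation(Z[rows, , drop = FALSE], dsS, yPred,
                                     k = min(k, length(rows) - 1L),
                                     split = sp, representation = name)
      if (sp == "valid") validReports[[it]] <- rep_ else testReports[[it]] <- rep_
    }
  }
  methods::new("TrialResult", spec = spec, config = cfg,
               validReports = validReports, testReports = testReports,
               meanValidMCC = mean(vapply(validReports, function(r) r@mcc, 1)),
               meanTestMCC = mean(vapply(testReports, function(r) r@mcc, 1)))
}

setMethod("show", "TrialResult", function(object) {
  cat(sprintf("TrialResult %s: %d iteration(s)\n", modelName(object@spec),
              length(object@validReports)))
  cat(sprintf("  mean valid MCC: %.3f   mean test MCC: %.3f\n",
              object@meanValidMCC, object@meanTestMCC))
})
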
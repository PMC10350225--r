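test_that("warmup trains only unsupervised components and never reads labels", {
  ds <- separableDataset()
  spec <- smallSpec("AE", "DANN", gamma = 1)
  m <- buildModel(spec, 10, 3, 2, seed = 1,
                  batchLevels = levels(batchLabels(ds)),
                  classLevels = c("c1", "c2"))
  cfg <- fastConfig(warmupEpochs = 5)
  m2 <- warmup(m, ds, cfg)
  # label classifier untouched, autoencoder moved
  expect_identical(m2@params$Wy, m@params$Wy)
  expect_identical(m2@params$by, m@params$by)
  expect_false(identical(m2@params$W1, m@params$W1))

  # class labels are never read: warmup succeeds with all labels masked
  masked <- ds
  SummarizedExperiment::colData(masked)$cls <- factor(NA_character_)
  SummarizedExperiment::colData(masked)$is_qc <- TRUE  # keep object valid
  m3 <- warmup(m, masked, cfg)
  expect_identical(m3@params$W1, m2@params$W1)

  # zero warmup epochs is the identity
  expect_identical(warmup(m, ds, fastConfig(warmupEpochs = 0)), m)
})

test_that("warmup reduces the reconstruction error on synthetic data", {
  ds <- normalizeDataset(
    generateSynthetic(SyntheticConfig(nSamples = 90, nFeatures = 20, seed = 2))$dataset,
    NormalizationSpec("standard"))
  spec <- smallSpec("AE")
  m <- buildModel(spec, 20, 3, 2, seed = 3, batchLevels = levels(batchLabels(ds)))
  X <- intensities(ds)
  idx <- as.integer(batchLabels(ds))
  recOf <- function(model) mean((decode(model, encode(model, X)$z, idx) - X)^2)
  m2 <- warmup(m, ds, fastConfig(warmupEpochs = 10))
  expect_lt(recOf(m2), recOf(m))
})

test_that("the frozen scenario leaves the autoencoder untouched", {
  ds <- separableDataset()
  split <- makeHoldoutSplits(ds, 1, seed = 4)[[1]]
  spec <- smallSpec("AE")
  m <- buildModel(spec, 10, 3, 2, seed = 5,
                  batchLevels = levels(batchLabels(ds)), classLevels = c("c1", "c2"))
  m <- warmup(m, ds, fastConfig(warmupEpochs = 2))
  fit <- trainScenario(m, split, ds, fastConfig(scenario = "frozen", maxEpochs = 5))
  for (nm in c("W1", "b1", "W2", "b2", "W3", "W4", "emb", "Wb1", "Wb2")) {
    expect_identical(fit$model@params[[nm]], m@params[[nm]], info = nm)
  }
  expect_false(identical(fit$model@params$Wy, m@params$Wy))
})

test_that("early stopping honors patience, the epoch cap and earlier-tie-break", {
  # stub history: best at epoch 3, no later improvement
  mcc <- c(0.2, 0.5, 0.8, 0.7, 0.7, 0.7, 0.6, 0.5, 0.4, 0.3)
  es <- earlyStopping(mcc, patience = 5, maxEpochs = 100)
  expect_equal(es$stopEpoch, 8)  # 8 - 3 >= 5
  expect_equal(es$bestEpoch, 3)
  # patience larger than the history: run to the cap
  es2 <- earlyStopping(mcc, patience = 100, maxEpochs = 10)
  expect_equal(es2$stopEpoch, 10)
  # ties keep the earlier epoch
  es3 <- earlyStopping(c(0.1, 0.9, 0.9, 0.9), patience = 10)
  expect_equal(es3$bestEpoch, 2)
  # the protocol defaults: patience 100 within a 1000-epoch cap on a long stub
  stub <- c(seq(0, 0.9, length.out = 50), rep(0.85, 200))
  es4 <- earlyStopping(stub, patience = 100, maxEpochs = 1000)
  expect_equal(es4$stopEpoch, 150)
  expect_equal(es4$bestEpoch, 50)
})

test_that("training stops once validation MCC stalls", {
  ds <- separableDataset(n = 90)
  split <- makeHoldoutSplits(ds, 1, seed = 6)[[1]]
  spec <- smallSpec("AE")
  m <- buildModel(spec, 10, 3, 2, seed = 7,
                  batchLevels = levels(batchLabels(ds)), classLevels = c("c1", "c2"))
  cfg <- fastConfig(maxEpochs = 60, patience = 4)
  fit <- trainScenario(warmup(m, ds, cfg), split, ds, cfg)
  # separable data saturates quickly; patience must kick in well before the cap
  expect_lt(fit$stopEpoch, 60)
  expect_gte(fit$stopEpoch - fit$bestEpoch, 4)
  expect_equal(max(fit$history$validMCC), fit$history$validMCC[fit$bestEpoch])
})

test_that("alternating training reaches high MCC on separable classes", {
  ds <- separableDataset(n = 90)
  split <- makeHoldoutSplits(ds, 1, seed = 8)[[1]]
  spec <- smallSpec("AE")
  m <- buildModel(spec, 10, 3, 2, seed = 9,
                  batchLevels = levels(batchLabels(ds)), classLevels = c("c1", "c2"))
  cfg <- fastConfig(maxEpochs = 40, patience = 40)
  fit <- trainScenario(warmup(m, ds, cfg), split, ds, cfg)
  assign <- splitAssignment(ds, split)
  rows <- which(assign == "train")
  pred <- predictClasses(fit$model, intensities(ds)[rows, ])
  expect_gt(matthewsCC(as.character(classLabels(ds))[rows], as.character(pred)), 0.9)
})

test_that("a single-class validation split is rejected by name", {
  ds <- separableDataset(n = 60)
  # force one batch to a single class, then make it the validation split
  cd <- SummarizedExperiment::colData(ds)
  cd$cls[cd$batch == "b2"] <- "c1"
  SummarizedExperiment::colData(ds) <- cd
  split <- methods::new("SplitPlan", iteration = 0L, seed = 1L,
                        trainBatches = "b1", validBatches = "b2", testBatches = "b3")
  m <- buildModel(smallSpec("AE"), 10, 3, 2, seed = 10,
                  batchLevels = c("b1", "b2", "b3"), classLevels = c("c1", "c2"))
  expect_error(trainScenario(m, split, ds, fastConfig()), "b2")
})

test_that("test labels are never read before evaluation", {
  ds <- separableDataset(n = 90)
  split <- makeHoldoutSplits(ds, 1, seed = 11)[[1]]
  cfg <- fastConfig(maxEpochs = 6)
  m <- buildModel(smallSpec("AE"), 10, 3, 2, seed = 12,
                  batchLevels = levels(batchLabels(ds)), classLevels = c("c1", "c2"))
  m <- warmup(m, ds, cfg)
  fit1 <- trainScenario(m, split, ds, cfg)

  # scramble the test-split labels: the trained parameters must be identical
  scrambled <- ds
  cd <- SummarizedExperiment::colData(scrambled)
  testRows <- which(cd$batch %in% split@testBatches)
  cd$cls[testRows] <- rev(cd$cls[testRows])
  SummarizedExperiment::colData(scrambled) <- cd
  fit2 <- trainScenario(m, split, scrambled, cfg)
  expect_identical(fit1$model@params, fit2$model@params)
})

test_that("repetitive holdout aggregates means and is deterministic", {
  ds <- separableDataset(n = 75, nBatches = 5)
  spec <- smallSpec("AE")
  cfg <- fastConfig(warmupEpochs = 2, maxEpochs = 4)
  tr <- runRepetitiveHoldout(ds, spec, cfg, nIterations = 3, seed = 13, k = 5)
  expect_length(tr@validReports, 3)
  expect_length(tr@testReports, 3)
  expect_equal(tr@meanValidMCC, mean(vapply(tr@validReports, function(r) r@mcc, 1)))
  expect_equal(tr@meanTestMCC, mean(vapply(tr@testReports, function(r) r@mcc, 1)))
  tr2 <- runRepetitiveHoldout(ds, spec, cfg, nIterations = 3, seed = 13, k = 5)
  expect_identical(vapply(tr@testReports, function(r) r@mcc, 1),
                   vapply(tr2@testReports, function(r) r@mcc, 1))
})

test_that("hyperparameter search selects by validation MCC only", {
  ds <- separableDataset(n = 75, nBatches = 5)
  space <- list(learningRate = list(min = 5e-4, max = 5e-3, log = TRUE),
                dropout = list(min = 0, max = 0.2))
  cfg <- fastConfig(warmupEpochs = 1, maxEpochs = 3)
  plans <- makeHoldoutSplits(ds, 1, seed = 14)
  res <- hyperparameterSearch(ds, "AE", "none", space = space, budget = 3,
                              baseConfig = cfg, nIterations = 1, seed = 14, k = 5,
                              splits = plans)
  expect_equal(res$strategy, "seeded random search")
  expect_equal(nrow(res$trials), 3)
  expect_equal(res$best@meanValidMCC, max(res$trials$meanValidMCC))

  # degenerate budget
  res1 <- hyperparameterSearch(ds, "AE", "none", space = space, budget = 1,
                               baseConfig = cfg, nIterations = 1, seed = 14, k = 5)
  expect_equal(nrow(res1$trials), 1)
  expect_error(hyperparameterSearch(ds, "AE", "none", budget = 0), "budget")

  # leakage guard: scrambling test labels must not change the selection
  scrambled <- ds
  cd <- SummarizedExperiment::colData(scrambled)
  testRows <- which(cd$batch %in% plans[[1]]@testBatches)
  cd$cls[testRows] <- withr::with_seed(99, sample(cd$cls[testRows]))
  SummarizedExperiment::colData(scrambled) <- cd
  res2 <- hyperparameterSearch(scrambled, "AE", "none", space = space, budget = 3,
                               baseConfig = cfg, nIterations = 1, seed = 14, k = 5,
                               splits = plans)
  expect_equal(which.max(res$trials$meanValidMCC), which.max(res2$trials$meanValidMCC))
})

test_that("baseline classifiers separate what is separable and not what is not", {
  ds <- separableDataset(n = 90)
  split <- makeHoldoutSplits(ds, 1, seed = 15)[[1]]
  X <- intensities(ds)
  res <- baselineClassify(X, ds, split, "linear-svm", k = 5)
  expect_equal(res$validReport@mcc, 1)
  rf <- baselineClassify(X, ds, split, "random-forest", k = 5, ntree = 100)
  expect_gt(rf$validReport@mcc, 0.9)

  # shuffled labels: chance-level MCC
  mccs <- sapply(1:5, function(s) {
    shuffled <- ds
    cd <- SummarizedExperiment::colData(shuffled)
    cd$cls <- withr::with_seed(s, sample(cd$cls))
    SummarizedExperiment::colData(shuffled) <- cd
    baselineClassify(intensities(shuffled), shuffled, split, "linear-svm",
                     k = 5, seed = s)$validReport@mcc
  })
  expect_lt(abs(mean(mccs)), 0.2)
})

test_that("balanced class weighting lifts minority recall on imbalanced data", {
  withr::with_seed(16, {
    n <- 200
    cls <- rep(c("major", "minor"), times = c(180, 20))
    batch <- rep(paste0("b", 1:4), length.out = n)
    X <- matrix(rnorm(n * 6, 0, 1.5), n, 6)
    X[cls == "minor", 1:2] <- X[cls == "minor", 1:2] + 1.6
    dimnames(X) <- list(sprintf("s%03d", 1:n), sprintf("f%d", 1:6))
    ds <- OmicsSet(X, batch = batch, cls = cls)
    split <- makeHoldoutSplits(ds, 1, seed = 17)[[1]]
    recallOf <- function(balanced) {
      res <- baselineClassify(X, ds, split, "linear-svm", balanced = balanced, k = 5)
      assign <- splitAssignment(ds, split)
      rows <- which(assign == "valid")
      truth <- as.character(classLabels(ds))[rows]
      mean(res$valid[truth == "minor"] == "minor")
    }
    expect_gte(recallOf(TRUE), recallOf(FALSE))
    expect_gt(recallOf(TRUE), 0)
  })
})

test_that("attributions are additive and vanish on irrelevant features", {
  withr::with_seed(18, {
    m <- buildModel(smallSpec("AE"), 6, 2, 2, seed = 19)
    Xb <- matrix(rnorm(60), 10, 6)
    Xe <- matrix(rnorm(30), 5, 6)
    A <- featureAttribution(m, Xb, Xe, classIndex = 2, nSteps = 256)
    lg <- predictLogits(m, Xe)[, 2]
    bg <- mean(predictLogits(m, Xb)[, 2])
    # completeness within 5% of the logit-gap scale
    expect_lt(max(abs(rowSums(A) - (lg - bg))), 0.05 * max(abs(lg - bg)))

    # a model whose logit depends on feature 1 only
    m1 <- m
    m1@params$W1[2:6, ] <- 0
    A1 <- featureAttribution(m1, Xb, Xe, classIndex = 2, nSteps = 32)
    expect_gt(mean(abs(A1[, 1])), 0)
    expect_equal(max(colMeans(abs(A1[, 2:6]))), 0)
    expect_error(featureAttribution(m, Xb[0, , drop = FALSE], Xe), "empty")
  })
})

test_that("attributions of a linear model match the closed form", {
  # a model that is exactly linear: identity-like encoder path with no relu
  # kinks in the probed region (use large positive biases)
  m <- buildModel(ModelSpec("AE", "none", layer1 = 6, layer2 = 6, bottleneck = 6),
                  4, 2, 2, seed = 20)
  withr::with_seed(21, {
    m@params$W1 <- cbind(diag(4), matrix(0, 4, 2))
    m@params$b1 <- rep(50, 6)  # keeps every relu active
    m@params$W2 <- rbind(diag(6))[, 1:6]
    m@params$b2 <- numeric(6)
    coef <- c(1.5, -2, 0.5, 0, 0, 0)
    m@params$Wy <- cbind(-coef, coef)
    m@params$by <- c(0, 0)
    Xb <- matrix(rnorm(20, 0, 0.5), 5, 4)
    Xe <- matrix(rnorm(8, 0, 0.5), 2, 4)
    A <- featureAttribution(m, Xb, Xe, classIndex = 2, nSteps = 16)
    expected <- sweep(Xe, 2, colMeans(Xb), "-") * matrix(coef[1:4], 2, 4, byrow = TRUE)
    expect_equal(as.numeric(A), as.numeric(expected), tolerance = 1e-8)
  })
})
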
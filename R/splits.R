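#' Batch-wise repetitive holdout split plans
#'
#' Randomly partitions the *batches* (never individual samples) of `ds` into
#' train/valid/test sets for each holdout iteration, so that validation and
#' test performance always measure generalization to batches unseen during
#' supervised training. The test set is resampled at every iteration; plans
#' are deterministic given `seed`.
#'
#' @param ds an [OmicsSet-class] (or a factor of batch labels).
#' @param nIterations number of holdout iterations.
#' @param validFraction,testFraction target fractions of *batches* assigned
#'   to the validation and test splits; each split always receives at least
#'   one batch.
#' @param seed integer seed.
#' @return a list of [SplitPlan-class] objects, one per iteration.
#' @export
makeHoldoutSplits <- function(ds, nIterations = 10, validFraction = 0.2,
                              testFraction = 0.2, seed = 1) {
  batches <- if (is(ds, "OmicsSet")) levels(batchLabels(ds)) else levels(factor(ds))
  K <- length(batches)
  if (K < 3) stopf("need at least 3 batches to form train/valid/test splits, got %d", K)
  if (validFraction <= 0 || testFraction <= 0 || validFraction + testFraction >= 1) {
    stopf("fractions must be in (0,1) with validFraction + testFraction < 1")
  }
  nValid <- max(1L, round(validFraction * K))
  nTest <- max(1L, round(testFraction * K))
  if (K - nValid - nTest < 1L) {
    nValid <- 1L
    nTest <- 1L
  }
  lapply(seq_len(nIterations), function(it) {
    perm <- withSeed(childSeed(seed, it), sample(batches))
    methods::new("SplitPlan",
                 iteration = as.integer(it - 1L), seed = as.integer(seed),
                 testBatches = perm[seq_len(nTest)],
                 validBatches = perm[nTest + seq_len(nValid)],
                 trainBatches = perm[(nTest + nValid + 1L):K])
  })
}

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan iteration %d (seed %d)\n", object@iteration, object@seed))
  cat(sprintf("  train: %s\n", paste(object@trainBatches, collapse = ", ")))
  cat(sprintf("  valid: %s\n", paste(object@validBatches, collapse = ", ")))
  cat(sprintf("  test:  %s\n", paste(object@testBatches, collapse = ", ")))
})

#' Which split does each sample fall in?
#'
#' A sample's split is a pure function of its batch.
#'
#' @param ds an [OmicsSet-class].
#' @param plan a [SplitPlan-class].
#' @return factor with levels `train`, `valid`, `test`, one entry per sample.
#' @export
splitAssignment <- function(ds, plan) {
  b <- as.character(batchLabels(ds))
  out <- rep(NA_character_, length(b))
  out[b %in% plan@trainBatches] <- "train"
  out[b %in% plan@validBatches] <- "valid"
  out[b %in% plan@testBatches] <- "test"
  if (any(is.na(out))) {
    stopf("batch(es) not covered by the split plan: %s",
          paste(unique(b[is.na(out)]), collapse = ", "))
  }
  factor(out, levels = c("train", "valid", "test"))
}

#' Inverse-frequency class weights
#'
#' Weight of each sample is the reciprocal of its class count; used to drive
#' weighted minibatch sampling during supervised training so minority-class
#' samples are seen as often as majority-class ones.
#'
#' @param cls a vector of class labels (`NA` entries get weight `NA`).
#' @return numeric vector of positive per-sample weights.
#' @export
classWeights <- function(cls) {
  if (length(cls) == 0) stopf("classWeights: empty label vector")
  f <- factor(cls)
  counts <- table(f)
  w <- as.numeric(1 / counts[as.character(f)])
  w
}
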
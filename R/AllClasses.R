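#' OmicsSet: a multi-batch omics intensity table with sample metadata
#'
#' `OmicsSet` extends [SummarizedExperiment::SummarizedExperiment] and is the
#' universal data currency of the package. The assay `"intensity"` stores
#' log-scale intensities with features as rows and samples as columns
#' (Bioconductor convention); user-facing functions and file I/O use the
#' samples-by-features orientation and [intensities()] transposes accordingly.
#' `colData` carries the per-sample metadata: `batch` (factor), `cls`
#' (condition factor, `NA` on QC samples), `is_qc` (logical) and optionally
#' `subject_id`.
#'
#' Validity requires: no `NA`/`NaN`/`Inf` intensities, every non-QC sample
#' has a condition label, and at least one batch level with at least one
#' sample.
#'
#' @seealso [OmicsSet()] for construction, [loadDataset()] for file input.
#' @export
setClass("OmicsSet", contains = "SummarizedExperiment")

setValidity("OmicsSet", function(object) {
  msgs <- character()
  cd <- SummarizedExperiment::colData(object)
  for (col in c("batch", "cls", "is_qc")) {
    if (!col %in% colnames(cd)) msgs <- c(msgs, sprintf("colData lacks required column '%s'", col))
  }
  if (length(msgs)) return(msgs)
  v <- SummarizedExperiment::assay(object)
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)
    msgs <- c(msgs, sprintf(
      "non-finite intensities at %d cell(s), first: feature '%s', sample '%s'",
      nrow(bad), rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  }
  qc <- as.logical(cd$is_qc)
  if (any(is.na(qc))) msgs <- c(msgs, "is_qc contains missing values")
  cls <- cd$cls
  if (!any(is.na(qc)) && any(is.na(cls[!qc]))) {
    msgs <- c(msgs, sprintf("%d non-QC sample(s) lack a cls label", sum(is.na(cls[!qc]))))
  }
  if (nlevels(factor(cd$batch)) < 1 || ncol(object) < 1) {
    msgs <- c(msgs, "dataset must contain at least one sample in at least one batch")
  }
  if (anyDuplicated(colnames(object))) msgs <- c(msgs, "sample IDs must be unique")
  if (anyDuplicated(rownames(object))) msgs <- c(msgs, "feature IDs must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct an OmicsSet from a samples-by-features matrix
#'
#' @param values numeric matrix, samples in rows, features in columns
#'   (log-scale intensities by convention).
#' @param batch per-sample batch labels (coerced to factor).
#' @param cls per-sample condition labels; `NA` allowed only on QC samples.
#' @param isQC logical per-sample QC flag (default all `FALSE`).
#' @param subjectID optional per-sample subject identifier.
#' @param sampleIDs,featureIDs identifiers; default to dimnames of `values`.
#' @return a validated [OmicsSet-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
#' ds <- OmicsSet(m, batch = c("b1", "b1", "b2"), cls = c("A", "B", "A"))
#' ds
#' @export
OmicsSet <- function(values, batch, cls = NULL, isQC = NULL, subjectID = NULL,
                     sampleIDs = rownames(values), featureIDs = colnames(values)) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(sampleIDs)) sampleIDs <- paste0("sample", seq_len(n))
  if (is.null(featureIDs)) featureIDs <- paste0("feature", seq_len(ncol(values)))
  if (length(batch) != n) stopf("length(batch) [%d] != number of samples [%d]", length(batch), n)
  if (is.null(isQC)) isQC <- rep(FALSE, n)
  if (is.null(cls)) cls <- rep(NA_character_, n)
  if (length(cls) != n || length(isQC) != n) {
    stopf("cls and isQC must each have one entry per sample (%d)", n)
  }
  cd <- S4Vectors::DataFrame(
    batch = factor(batch),
    cls = factor(cls),
    is_qc = as.logical(isQC),
    row.names = sampleIDs)
  if (!is.null(subjectID)) cd$subject_id <- as.character(subjectID)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(values)),
    colData = cd)
  rownames(se) <- featureIDs
  colnames(se) <- sampleIDs
  methods::new("OmicsSet", se)
}

#' One cell of the model grid: backbone, batch-removal head and loss weights
#'
#' A `ModelSpec` identifies one of the ten models in the grid (two backbones
#' `AE`/`VAE` crossed with five batch-removal strategies) plus the
#' architecture and loss-weight hyperparameters shared by all of them.
#'
#' Slots:
#' \describe{
#'   \item{backbone}{`"AE"` or `"VAE"`.}
#'   \item{removal}{one of `"none"`, `"DANN"`, `"NormAE"`, `"invTriplet"`,
#'     `"revTriplet"`.}
#'   \item{layer1}{encoder hidden width (mirrored in the decoder).}
#'   \item{layer2}{decoder hidden width.}
#'   \item{bottleneck}{embedding dimension.}
#'   \item{dropout}{dropout probability on hidden layers, in `[0, 1)`.}
#'   \item{margin}{triplet margin \eqn{\alpha}; required for the triplet
#'     removals, ignored otherwise.}
#'   \item{beta}{KL weight \eqn{\beta}; used only by the VAE backbone.}
#'   \item{gamma}{batch-removal loss weight \eqn{\gamma} (also the gradient
#'     reversal strength \eqn{\lambda_b}).}
#'   \item{labelSmoothing}{label smoothing for the condition classifier.}
#'   \item{useBatchMapping}{add a learned batch-ID vector to the bottleneck
#'     before decoding.}
#'   \item{zReg}{L2 activity regularization of the embedding (AE backbone
#'     only; the VAE's KL term plays this role there). Applied
#'     optimizer-side, like weight decay, during unsupervised passes; it
#'     keeps the embedding scale bounded so the adversarial batch-removal
#'     game is played in a compact space.}
#' }
#' @export
setClass("ModelSpec", representation(
  backbone = "character", removal = "character",
  layer1 = "integer", layer2 = "integer", bottleneck = "integer",
  dropout = "numeric", margin = "numeric", beta = "numeric",
  gamma = "numeric", labelSmoothing = "numeric", useBatchMapping = "logical",
  zReg = "numeric"))

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (!object@backbone %in% c("AE", "VAE")) {
    msgs <- c(msgs, sprintf("unknown backbone '%s'", object@backbone))
  }
  removals <- c("none", "DANN", "NormAE", "invTriplet", "revTriplet")
  if (!object@removal %in% removals) {
    msgs <- c(msgs, sprintf("unknown removal '%s' (valid: %s)", object@removal,
                            paste(removals, collapse = ", ")))
  }
  if (object@removal %in% c("invTriplet", "revTriplet") &&
      (is.na(object@margin) || object@margin < 0)) {
    msgs <- c(msgs, sprintf("removal '%s' requires a non-negative margin", object@removal))
  }
  if (object@backbone == "VAE" && (is.na(object@beta) || object@beta < 0)) {
    msgs <- c(msgs, "VAE backbone requires a non-negative beta")
  }
  if (object@dropout < 0 || object@dropout >= 1) msgs <- c(msgs, "dropout must be in [0, 1)")
  if (object@labelSmoothing < 0 || object@labelSmoothing >= 1) {
    msgs <- c(msgs, "labelSmoothing must be in [0, 1)")
  }
  if (any(c(object@layer1, object@layer2, object@bottleneck) < 1)) {
    msgs <- c(msgs, "layer widths and bottleneck must be positive")
  }
  if (object@gamma < 0) msgs <- c(msgs, "gamma must be non-negative")
  if (is.na(object@zReg) || object@zReg < 0) msgs <- c(msgs, "zReg must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' A trained (or freshly initialized) model of the suite
#'
#' Holds the [ModelSpec-class], the parameter list (encoder, decoder, batch
#' classifier, label classifier, batch embedding table) and the data
#' dimensions it was built for. Construct with [buildModel()].
#'
#' @export
setClass("DebatchModel", representation(
  spec = "ModelSpec", params = "list",
  nFeatures = "integer", nBatches = "integer", nClasses = "integer",
  batchLevels = "character", classLevels = "character", seed = "integer"))

#' Batch-level train/valid/test assignment for one holdout iteration
#'
#' Whole batches are assigned to exactly one of the three splits so that
#' validation and test performance measure generalization to batches never
#' seen during supervised training.
#'
#' @export
setClass("SplitPlan", representation(
  iteration = "integer", seed = "integer",
  trainBatches = "character", validBatches = "character", testBatches = "character"))

setValidity("SplitPlan", function(object) {
  msgs <- character()
  sets <- list(object@trainBatches, object@validBatches, object@testBatches)
  if (any(lengths(sets) == 0)) msgs <- c(msgs, "each split must contain at least one batch")
  all_b <- unlist(sets)
  if (anyDuplicated(all_b)) msgs <- c(msgs, "splits must be pairwise disjoint")
  if (length(msgs)) msgs else TRUE
})

#' Batch-mixing, QC and classification metrics for one representation
#'
#' Scalar metrics for one representation of one split: normalized batch
#' entropy `nBE` (0 = perfect mixing, 1 = perfect batch separation),
#' chance-adjusted partition scores `ARI`/`AMI` between k-NN batch
#' predictions and true batches, QC replicate tightness `aPCC`/`nMED`
#' (`NA` when the data carry no QC samples), and `mcc`/`accuracy` of the
#' supplied class predictions (`NA` when no predictions are supplied).
#'
#' @export
setClass("MetricsReport", representation(
  nBE = "numeric", ARI = "numeric", AMI = "numeric",
  aPCC = "numeric", nMED = "numeric", mcc = "numeric", accuracy = "numeric",
  split = "character", representation = "character"))

#' Configuration of the synthetic multi-batch generator
#'
#' See [SyntheticConfig()] for the constructor and defaults.
#' @export
setClass("SyntheticConfig", representation(
  nSamples = "integer", nFeatures = "integer", nBatches = "integer",
  classProportions = "numeric", nInformative = "integer", effectSize = "numeric",
  batchShiftSD = "numeric", batchScaleSD = "numeric", noiseSD = "numeric",
  nQCPerBatch = "integer", confounding = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  if (abs(sum(object@classProportions) - 1) > 1e-8) {
    msgs <- c(msgs, "classProportions must sum to 1")
  }
  if (length(object@classProportions) < 2) msgs <- c(msgs, "need at least 2 classes")
  if (object@nInformative > object@nFeatures) {
    msgs <- c(msgs, "nInformative cannot exceed nFeatures")
  }
  if (any(c(object@batchShiftSD, object@batchScaleSD, object@noiseSD) < 0)) {
    msgs <- c(msgs, "standard deviations must be non-negative")
  }
  if (object@nQCPerBatch < 0) msgs <- c(msgs, "nQCPerBatch must be >= 0")
  if (object@confounding < 0 || object@confounding > 1) {
    msgs <- c(msgs, "confounding must be in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' Slots record the exact per-batch additive location shifts and
#' multiplicative scale factors, the baseline log-intensity profile, the
#' indices of class-informative features and the per-class mean vectors on
#' those features. Used by recovery tests and by downstream sanity checks.
#'
#' @export
setClass("SyntheticGroundTruth", representation(
  batchLocation = "matrix", batchScale = "matrix", baseline = "numeric",
  informativeFeatures = "integer", classMeans = "matrix"))

#' Training protocol configuration
#'
#' See [TrainConfig()] for defaults; the defaults mirror the study protocol
#' (minibatch size 32, up to 1000 post-warmup epochs, early stopping with
#' patience 100 on validation MCC).
#'
#' @export
setClass("TrainConfig", representation(
  scenario = "character", warmupEpochs = "integer", maxEpochs = "integer",
  patience = "integer", batchSize = "integer", learningRate = "numeric",
  weightDecay = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (!object@scenario %in% c("frozen", "alternating")) {
    msgs <- c(msgs, sprintf("unknown scenario '%s'", object@scenario))
  }
  if (object@warmupEpochs < 0) msgs <- c(msgs, "warmupEpochs must be >= 0")
  if (object@patience > object@maxEpochs) msgs <- c(msgs, "patience cannot exceed maxEpochs")
  if (object@learningRate <= 0 || object@weightDecay < 0) {
    msgs <- c(msgs, "learningRate must be > 0 and weightDecay >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of training one model specification over repeated holdouts
#'
#' @export
setClass("TrialResult", representation(
  spec = "ModelSpec", config = "TrainConfig",
  validReports = "list", testReports = "list",
  meanValidMCC = "numeric", meanTestMCC = "numeric"))
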
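#' Classical baseline classifiers on a non-neural representation
#'
#' Fits a linear support vector machine or a random forest on the non-QC
#' labeled samples of the training batches, with class weights inversely
#' proportional to class frequencies (the "balanced" convention), then
#' predicts the validation and test batches and assembles the full metrics
#' panel in the supplied feature space.
#'
#' @param X representation matrix, rows aligned to the samples of `ds`
#'   (typically [intensities()] of a raw or normalized dataset).
#' @param ds the [OmicsSet-class].
#' @param split a [SplitPlan-class].
#' @param kind `"linear-svm"` or `"random-forest"`.
#' @param cost linear-SVM cost parameter.
#' @param ntree random-forest tree count.
#' @param k probe neighbour count for the metric panel.
#' @param balanced apply inverse-frequency class weights (default `TRUE`).
#' @param seed seed for the random-forest fit.
#' @return list with factors `valid`/`test` (predictions), the fitted
#'   `model`, and [MetricsReport-class] objects `validReport`/`testReport`.
#' @export
baselineClassify <- function(X, ds, split, kind = c("linear-svm", "random-forest"),
                             cost = 1, ntree = 200, k = 20, balanced = TRUE, seed = 1) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (nrow(X) != ncol(ds)) {
    stopf("representation has %d rows but dataset has %d samples", nrow(X), ncol(ds))
  }
  assign <- splitAssignment(ds, split)
  cls <- factor(classLabels(ds))
  trainRows <- which(assign == "train" & !isQC(ds) & !is.na(cls))
  if (length(unique(cls[trainRows])) < 2) {
    stopf("training split has a single class; cannot fit a classifier")
  }
  yTrain <- droplevels(cls[trainRows])
  wts <- 1 / table(yTrain)
  wts <- wts / sum(wts) * nlevels(yTrain)

  fit <- withSeed(seed, {
    if (kind == "linear-svm") {
      e1071::svm(x = X[trainRows, , drop = FALSE], y = yTrain, kernel = "linear",
                 cost = cost, scale = FALSE,
                 class.weights = if (balanced) wts else NULL)
    } else {
      randomForest::randomForest(x = X[trainRows, , drop = FALSE], y = yTrain,
                                 ntree = ntree,
                                 classwt = if (balanced) as.numeric(wts) else NULL)
    }
  })

  out <- list(model = fit, kind = kind)
  for (sp in c("valid", "test")) {
    rows <- which(assign == sp)
    pred <- predict(fit, X[rows, , drop = FALSE])
    out[[sp]] <- pred
    out[[paste0(sp, "Report")]] <- evaluateRepresentation(
      X[rows, , drop = FALSE], ds[, rows], yPred = pred,
      k = min(k, length(rows) - 1L), split = sp, representation = "features")
  }
  out
}
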
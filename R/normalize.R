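#' Normalization specification
#'
#' The three scalers of the benchmark — `minmax` (per-feature rescale to
#' `[0, 1]`), `standard` (z-score: zero mean, unit variance per feature) and
#' `robust` (center by median, scale by interquartile range) — each either
#' fit on the whole dataset (`perBatch = FALSE`) or independently within
#' every batch (`perBatch = TRUE`). The per-batch z-score forces every batch
#' to mean 0 and unit variance per feature, which is itself a simple batch
#' correction.
#'
#' @param method one of `"minmax"`, `"standard"`, `"robust"`.
#' @param perBatch fit scaling statistics within each batch independently.
#' @return a `NormalizationSpec` object.
#' @export
NormalizationSpec <- function(method = c("standard", "minmax", "robust"), perBatch = FALSE) {
  method <- match.arg(method)
  methods::new("NormalizationSpec", method = method, perBatch = isTRUE(perBatch))
}

#' @export
setClass("NormalizationSpec", representation(method = "character", perBatch = "logical"))

setMethod("show", "NormalizationSpec", function(object) {
  cat(sprintf("NormalizationSpec: %s%s\n", object@method,
              if (object@perBatch) " (per batch)" else " (global)"))
})

#' Normalize an omics dataset
#'
#' Applies the scaler described by `spec` feature-wise within each fit group
#' (the whole dataset, or each batch when `spec@perBatch`). QC samples are
#' transformed with the statistics of the group they belong to. Features
#' with zero variance / zero IQR / zero range within a fit group are
#' centered only, i.e. map to 0 (avoids division by zero).
#'
#' @param ds an [OmicsSet-class].
#' @param spec a [NormalizationSpec()].
#' @return a normalized [OmicsSet-class] with identical metadata.
#' @export
normalizeDataset <- function(ds, spec) {
  stopifnot(is(ds, "OmicsSet"), is(spec, "NormalizationSpec"))
  values <- intensities(ds)
  batch <- batchLabels(ds)
  if (spec@perBatch) {
    sizes <- table(batch)
    if (spec@method %in% c("standard", "robust") && any(sizes < 2)) {
      stopf("per-batch %s normalization requires >= 2 samples per batch; batch '%s' has %d",
            spec@method, names(sizes)[which.min(sizes)], min(sizes))
    }
    for (b in levels(batch)) {
      idx <- which(batch == b)
      values[idx, ] <- scaleBlock(values[idx, , drop = FALSE], spec@method)
    }
  } else {
    values <- scaleBlock(values, spec@method)
  }
  setIntensities(ds, values)
}

# Scale one fit group feature-wise; zero-spread features map to 0.
scaleBlock <- function(x, method) {
  center <- switch(method,
    standard = colMeans(x),
    robust = apply(x, 2, median),
    minmax = apply(x, 2, min))
  scale <- switch(method,
    standard = apply(x, 2, sd),
    robust = apply(x, 2, function(col) diff(quantile(col, c(0.25, 0.75), names = FALSE))),
    minmax = apply(x, 2, function(col) diff(range(col))))
  scale[!is.finite(scale) | scale == 0] <- 1
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}
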
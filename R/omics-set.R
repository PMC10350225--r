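#' @rdname OmicsSet-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname OmicsSet-accessors
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))
#' @rdname OmicsSet-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname OmicsSet-accessors
#' @export
setGeneric("isQC", function(x) standardGeneric("isQC"))
#' @rdname OmicsSet-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname OmicsSet-accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' Accessors for OmicsSet
#'
#' `intensities()` returns the samples-by-features matrix (the transpose of
#' the internal assay); `batchLabels()` and `classLabels()` return factors
#' (class is `NA` on QC samples); `isQC()` a logical vector; `sampleIDs()`
#' and `featureIDs()` the identifiers.
#'
#' @param x an [OmicsSet-class].
#' @return see description.
#' @name OmicsSet-accessors
NULL

#' @rdname OmicsSet-accessors
setMethod("intensities", "OmicsSet", function(x) t(SummarizedExperiment::assay(x, "intensity")))
#' @rdname OmicsSet-accessors
setMethod("batchLabels", "OmicsSet", function(x) factor(SummarizedExperiment::colData(x)$batch))
#' @rdname OmicsSet-accessors
setMethod("classLabels", "OmicsSet", function(x) SummarizedExperiment::colData(x)$cls)
#' @rdname OmicsSet-accessors
setMethod("isQC", "OmicsSet", function(x) SummarizedExperiment::colData(x)$is_qc)
#' @rdname OmicsSet-accessors
setMethod("sampleIDs", "OmicsSet", function(x) colnames(x))
#' @rdname OmicsSet-accessors
setMethod("featureIDs", "OmicsSet", function(x) rownames(x))

setMethod("show", "OmicsSet", function(object) {
  b <- batchLabels(object)
  cat(sprintf("OmicsSet: %d samples x %d features\n", ncol(object), nrow(object)))
  cat(sprintf("  batches: %d (%s)\n", nlevels(b),
              paste(head(levels(b), 6), collapse = ", ")))
  cls <- classLabels(object)
  cat(sprintf("  classes: %s\n",
              paste(levels(factor(cls)), collapse = ", ")))
  cat(sprintf("  QC samples: %d\n", sum(isQC(object))))
})

#' Replace the intensity values of an OmicsSet
#'
#' Returns a copy of `ds` whose intensities are `values` (samples x
#' features), keeping all metadata. Used by normalization and by decoders
#' exporting corrected features.
#'
#' @param ds an [OmicsSet-class].
#' @param values numeric matrix, samples x features, dimensions matching `ds`.
#' @return an [OmicsSet-class].
#' @export
setIntensities <- function(ds, values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(ds) || ncol(values) != nrow(ds)) {
    stopf("replacement matrix is %dx%d but dataset has %d samples x %d features",
          nrow(values), ncol(values), ncol(ds), nrow(ds))
  }
  SummarizedExperiment::assay(ds, "intensity") <- t(values)
  validObject(ds)
  ds
}
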
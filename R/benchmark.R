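#' Result table of a benchmark run
#'
#' One row per (method, iteration, split): neural grid cells are scored in
#' their bottleneck embedding space, normalization baselines in feature
#' space. Every (method, iteration, split) triple appears exactly once.
#'
#' @export
setClass("BenchmarkResult", representation(rows = "data.frame", seed = "integer"))

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf("BenchmarkResult: %d rows, %d method(s), %d iteration(s)\n",
              nrow(object@rows), length(unique(object@rows$method)),
              length(unique(object@rows$iteration))))
})

#' @rdname benchmarkRows
#' @export
setGeneric("benchmarkRows", function(x) standardGeneric("benchmarkRows"))

#' Tidy rows of a BenchmarkResult
#'
#' @param x a [BenchmarkResult-class].
#' @return the underlying tidy `data.frame`.
#' @name benchmarkRows
#' @export
setMethod("benchmarkRows", "BenchmarkResult", function(x) x@rows)

baselineMethods <- function() {
  c("raw", "minmax", "standard", "robust",
    "minmax_per_batch", "standard_per_batch", "robust_per_batch")
}

#' Run the comparative benchmark
#'
#' End-to-end workflow: load or simulate a dataset, draw shared batch-level
#' holdout splits, run every requested method — raw data, the three global
#' and three per-batch normalizations (each scored by a classical
#' classifier in feature space), and any of the ten neural grid cells
#' (scored in embedding space via [runRepetitiveHoldout()]) — and collect
#' one metrics row per method, iteration and split. With `outputDir` set,
#' writes `benchmark.csv`, `benchmark.json` and `summary.csv`.
#'
#' @param config a configuration list or the path of a YAML file with the
#'   sections `dataset` (either `synthetic:` generator settings or
#'   `files: {matrix:, metadata:}`), `methods` (character vector),
#'   `nIterations`, `seed`, and optional `train`, `model`, `baseline`
#'   overrides.
#' @param outputDir optional directory for report files.
#' @return a [BenchmarkResult-class].
#' @export
runBenchmark <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  nIterations <- as.integer(config$nIterations %||% 3L)

  ds <- benchmarkDataset(config$dataset, seed)
  known <- c(baselineMethods(), names(modelGrid()))
  methodsReq <- as.character(config$methods %||% known)
  bad <- setdiff(methodsReq, known)
  if (length(bad)) {
    stopf("unknown method(s): %s\n  valid methods: %s",
          paste(bad, collapse = ", "), paste(known, collapse = ", "))
  }

  splits <- makeHoldoutSplits(ds, nIterations,
                              validFraction = config$validFraction %||% 0.2,
                              testFraction = config$testFraction %||% 0.2,
                              seed = seed)
  k <- as.integer(config$k %||% 20L)
  baseKind <- config$baseline$kind %||% "linear-svm"
  trainArgs <- config$train %||% list()
  modelArgs <- config$model %||% list()

  rows <- list()
  for (method in methodsReq) {
    if (method %in% baselineMethods()) {
      dsm <- if (method == "raw") ds else {
        normalizeDataset(ds, NormalizationSpec(
          method = sub("_per_batch$", "", method),
          perBatch = grepl("_per_batch$", method)))
      }
      Xm <- intensities(dsm)
      for (it in seq_along(splits)) {
        res <- baselineClassify(Xm, dsm, splits[[it]], kind = baseKind, k = k,
                                seed = childSeed(seed, 600L + it))
        rows[[length(rows) + 1L]] <- reportAsRow(res$validReport, method = method,
                                                 iteration = it - 1L)
        rows[[length(rows) + 1L]] <- reportAsRow(res$testReport, method = method,
                                                 iteration = it - 1L)
      }
    } else {
      cell <- strsplit(method, "-", fixed = TRUE)[[1]]
      specArgs <- modelArgs
      specArgs$backbone <- cell[1]
      specArgs$removal <- cell[2]
      if (cell[2] %in% c("invTriplet", "revTriplet") && is.null(specArgs$margin)) {
        specArgs$margin <- 1
      }
      spec <- do.call(ModelSpec, specArgs)
      cfg <- do.call(TrainConfig, modifyList(list(seed = seed), trainArgs))
      trial <- runRepetitiveHoldout(ds, spec, cfg, nIterations = nIterations,
                                    seed = seed, splits = splits, k = k)
      for (it in seq_along(splits)) {
        rows[[length(rows) + 1L]] <- reportAsRow(trial@validReports[[it]],
                                                 method = method, iteration = it - 1L)
        rows[[length(rows) + 1L]] <- reportAsRow(trial@testReports[[it]],
                                                 method = method, iteration = it - 1L)
      }
    }
  }
  result <- methods::new("BenchmarkResult", rows = do.call(rbind, rows), seed = seed)
  if (!is.null(outputDir)) writeBenchmark(result, outputDir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

benchmarkDataset <- function(datasetCfg, seed) {
  if (is.null(datasetCfg)) stopf("config lacks a 'dataset' section")
  if (!is.null(datasetCfg$files)) {
    return(loadDataset(datasetCfg$files$matrix, datasetCfg$files$metadata))
  }
  syn <- datasetCfg$synthetic %||% list()
  if (is.null(syn$seed)) syn$seed <- seed
  generateSynthetic(do.call(SyntheticConfig, syn))$dataset
}

#' Per-method summary and ranking of a benchmark
#'
#' Mean and standard deviation of every metric per method and split over
#' the holdout iterations (SD is 0 by convention for a single iteration);
#' methods are ranked by mean validation MCC, so the batch-mixing and QC
#' columns describe the models selected for classification performance.
#'
#' @param result a [BenchmarkResult-class].
#' @return a `data.frame`, one row per method, ranked by mean valid MCC.
#' @export
summarizeBenchmark <- function(result) {
  rows <- benchmarkRows(result)
  if (!nrow(rows)) stopf("empty benchmark result")
  metrics <- c("nBE", "ARI", "AMI", "aPCC", "nMED", "mcc", "accuracy")
  out <- list()
  for (method in unique(rows$method)) {
    rec <- list(method = method)
    for (sp in c("valid", "test")) {
      sub <- rows[rows$method == method & rows$split == sp, , drop = FALSE]
      for (m in metrics) {
        v <- sub[[m]]
        rec[[paste0(sp, "_", m, "_mean")]] <- mean(v)
        rec[[paste0(sp, "_", m, "_sd")]] <- if (length(v) > 1) sd(v) else 0
      }
    }
    out[[method]] <- as.data.frame(rec)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(-tab$valid_mcc_mean), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Write benchmark report files
#'
#' @param result a [BenchmarkResult-class].
#' @param outputDir directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeBenchmark <- function(result, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(benchmarkRows(result), file.path(outputDir, "benchmark.csv"))
  jsonlite::write_json(benchmarkRows(result), file.path(outputDir, "benchmark.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  data.table::fwrite(summarizeBenchmark(result), file.path(outputDir, "summary.csv"))
  invisible(outputDir)
}

#' Corrected feature table from a trained model's decoder
#'
#' Reconstructs every sample from its bottleneck embedding *without* the
#' batch-mapping vector, yielding a nominally batch-free feature-space
#' table. Provided for interoperability only and not recommended for
#' downstream analysis: the decoder cannot improve on the bottleneck
#' representation, and the reconstruction objective is only one of several
#' competing losses, so the utility of these values is not guaranteed.
#' Prefer the bottleneck embedding plus [featureAttribution()].
#'
#' @param model a trained [DebatchModel-class].
#' @param ds the [OmicsSet-class] to correct.
#' @return an [OmicsSet-class] with reconstructed intensities.
#' @export
correctedFeatures <- function(model, ds) {
  Z <- encode(model, intensities(ds))$z
  Xhat <- decForward(model, Z, batchIdx = NULL, training = FALSE)$Xhat
  dimnames(Xhat) <- dimnames(intensities(ds))
  setIntensities(ds, Xhat)
}
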
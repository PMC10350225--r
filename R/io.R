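#' Load an omics dataset from an intensity matrix and a metadata table
#'
#' Reads a CSV/TSV intensity matrix (sample rows, feature columns, first
#' column holding the sample ID) and a CSV/TSV metadata table with columns
#' `sample_id`, `batch`, `cls`, `is_qc` and optionally `subject_id`, joins
#' them on sample ID and returns a validated [OmicsSet-class]. Values are
#' used as stored: no implicit log transform is applied.
#'
#' @param matrixPath path to the intensity matrix (field separator inferred).
#' @param metadataPath path to the sample metadata table.
#' @param transpose set `TRUE` if the matrix file stores features as rows and
#'   samples as columns; the canonical orientation is samples x features.
#' @return an [OmicsSet-class]; sample order follows the matrix file.
#' @export
loadDataset <- function(matrixPath, metadataPath, transpose = FALSE) {
  mat_dt <- data.table::fread(matrixPath, header = TRUE, data.table = FALSE)
  if (ncol(mat_dt) < 2) stopf("matrix file '%s' has no feature columns", matrixPath)
  ids <- as.character(mat_dt[[1]])
  values <- as.matrix(mat_dt[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  if (transpose) values <- t(values)

  meta <- data.table::fread(metadataPath, header = TRUE, data.table = FALSE)
  required <- c("sample_id", "batch", "cls", "is_qc")
  missing_cols <- setdiff(required, colnames(meta))
  if (length(missing_cols)) {
    stopf("metadata schema error: missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)

  only_matrix <- setdiff(rownames(values), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, rownames(values))
  if (length(only_matrix) || length(only_meta)) {
    stopf(paste0("join error: %d sample(s) only in matrix, %d only in metadata ",
                 "(matrix n=%d, metadata n=%d)"),
          length(only_matrix), length(only_meta), nrow(values), nrow(meta))
  }
  meta <- meta[match(rownames(values), meta$sample_id), , drop = FALSE]

  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    cells <- apply(head(bad, 5), 1, function(rc) {
      sprintf("[sample '%s', feature '%s']", rownames(values)[rc[1]], colnames(values)[rc[2]])
    })
    stopf("validation error: %d non-finite value(s) in matrix, e.g. %s",
          nrow(bad), paste(cells, collapse = ", "))
  }

  qc <- parseQCFlag(meta$is_qc)
  cls <- as.character(meta$cls)
  cls[qc & !is.na(cls) & cls == ""] <- NA
  cls[cls == ""] <- NA
  OmicsSet(values,
           batch = meta$batch, cls = cls, isQC = qc,
           subjectID = if ("subject_id" %in% colnames(meta)) meta$subject_id else NULL,
           sampleIDs = rownames(values), featureIDs = colnames(values))
}

parseQCFlag <- function(x) {
  x_chr <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("1", "true", "t", "yes")] <- TRUE
  out[x_chr %in% c("0", "false", "f", "no")] <- FALSE
  if (any(is.na(out))) {
    stopf("is_qc contains unparseable value(s): %s",
          paste(unique(x_chr[is.na(out)]), collapse = ", "))
  }
  out
}

#' Write an OmicsSet to an intensity CSV and a metadata CSV
#'
#' Inverse of [loadDataset()]: the matrix file holds samples as rows (first
#' column `sample_id`), the metadata file the columns `sample_id`, `batch`,
#' `cls`, `is_qc` (0/1) and, when present, `subject_id`.
#'
#' @param ds an [OmicsSet-class].
#' @param matrixPath,metadataPath output file paths.
#' @return invisibly, the two paths.
#' @export
writeDataset <- function(ds, matrixPath, metadataPath) {
  values <- intensities(ds)
  out <- data.frame(sample_id = rownames(values), values, check.names = FALSE)
  data.table::fwrite(out, matrixPath)
  cd <- SummarizedExperiment::colData(ds)
  meta <- data.frame(
    sample_id = rownames(cd),
    batch = as.character(cd$batch),
    cls = as.character(cd$cls),
    is_qc = as.integer(cd$is_qc))
  if ("subject_id" %in% colnames(cd)) meta$subject_id <- as.character(cd$subject_id)
  data.table::fwrite(meta, metadataPath)
  invisible(c(matrixPath, metadataPath))
}

#' Serialize split plans to JSON
#'
#' @param plans a list of [SplitPlan-class] objects.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
writeSplitPlans <- function(plans, path) {
  payload <- lapply(plans, function(p) list(
    iteration = p@iteration, seed = p@seed,
    train_batches = p@trainBatches,
    valid_batches = p@validBatches,
    test_batches = p@testBatches))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read split plans from JSON written by [writeSplitPlans()]
#'
#' @param path JSON path.
#' @return a list of [SplitPlan-class] objects.
#' @export
readSplitPlans <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    methods::new("SplitPlan",
                 iteration = as.integer(payload$iteration[[i]]),
                 seed = as.integer(payload$seed[[i]]),
                 trainBatches = as.character(unlist(payload$train_batches[[i]])),
                 validBatches = as.character(unlist(payload$valid_batches[[i]])),
                 testBatches = as.character(unlist(payload$test_batches[[i]])))
  })
}
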
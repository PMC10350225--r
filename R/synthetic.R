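#' Configuration for the synthetic multi-batch generator
#'
#' Defaults describe a moderate three-batch LC-MS-like study on the log
#' scale: 300 samples, 200 features, two balanced classes, 10% informative
#' features (20 at the defaults) with a one-log-unit class effect, per-batch
#' per-feature additive
#' location shifts of SD 1, mild multiplicative per-batch scale distortion
#' (SD 0.05 on the log of the factor), unit residual noise and 2 pooled QC
#' injections per batch.
#'
#' @param nSamples,nFeatures,nBatches dimensions of the generated table.
#' @param classProportions probability vector over the (>= 2) classes.
#' @param nInformative number of class-informative features.
#' @param effectSize mean log-intensity difference between consecutive
#'   classes on informative features.
#' @param batchShiftSD SD of the per-batch, per-feature additive location
#'   shifts (log scale).
#' @param batchScaleSD SD of the log of the per-batch, per-feature
#'   multiplicative scale factors.
#' @param noiseSD residual within-batch SD.
#' @param nQCPerBatch pooled QC replicates injected per batch.
#' @param confounding in `[0, 1]`: probability that a sample's class is
#'   dictated by its batch instead of drawn independently (0 = class
#'   orthogonal to batch, the default).
#' @param seed integer seed; generation is fully deterministic given the
#'   configuration.
#' @return a [SyntheticConfig-class].
#' @export
SyntheticConfig <- function(nSamples = 300, nFeatures = 200, nBatches = 3,
                            classProportions = c(0.5, 0.5),
                            nInformative = max(1, ceiling(nFeatures / 10)),
                            effectSize = 1, batchShiftSD = 1, batchScaleSD = 0.05,
                            noiseSD = 1, nQCPerBatch = 2, confounding = 0, seed = 1) {
  methods::new("SyntheticConfig",
               nSamples = as.integer(nSamples), nFeatures = as.integer(nFeatures),
               nBatches = as.integer(nBatches),
               classProportions = as.numeric(classProportions),
               nInformative = as.integer(nInformative), effectSize = as.numeric(effectSize),
               batchShiftSD = as.numeric(batchShiftSD), batchScaleSD = as.numeric(batchScaleSD),
               noiseSD = as.numeric(noiseSD), nQCPerBatch = as.integer(nQCPerBatch),
               confounding = as.numeric(confounding), seed = as.integer(seed))
}

#' Generate a synthetic multi-batch omics dataset with known ground truth
#'
#' Log intensities are assembled per sample `i` (batch `b`, class `c`) and
#' feature `j` as
#' \deqn{y_{ij} = (\mu_j + \delta_{cj} + \epsilon_{ij} + L_{bj}) \cdot S_{bj}}
#' where \eqn{\mu_j} is a baseline profile, \eqn{\delta_{cj}} the class
#' effect on informative features, \eqn{L_{bj} \sim N(0, \sigma_L^2)} the
#' additive per-batch location shift, \eqn{S_{bj} = \exp(N(0, \sigma_S^2))}
#' the multiplicative per-batch scale factor and \eqn{\epsilon} Gaussian
#' noise. Batch effects are drawn independently per batch x feature, so
#' drift is analyte-specific, as in real LC-MS data. QC samples are
#' replicates of the fixed baseline profile subjected to the same batch
#' effects and fresh noise.
#'
#' @param cfg a [SyntheticConfig()].
#' @return a list with elements `dataset` ([OmicsSet-class]) and `truth`
#'   ([SyntheticGroundTruth-class]).
#' @export
generateSynthetic <- function(cfg) {
  validObject(cfg)
  withSeed(cfg@seed, {
    K <- cfg@nBatches
    p <- cfg@nFeatures
    nC <- length(cfg@classProportions)

    baseline <- rnorm(p, mean = 20, sd = 2)
    informative <- sort(sample.int(p, cfg@nInformative))
    # class c gets offset (c-1) * effectSize on informative features
    classEffect <- matrix(0, nC, p)
    for (cc in seq_len(nC)) classEffect[cc, informative] <- (cc - 1) * cfg@effectSize
    batchLoc <- matrix(rnorm(K * p, 0, cfg@batchShiftSD), K, p)
    batchScale <- matrix(exp(rnorm(K * p, 0, cfg@batchScaleSD)), K, p)

    batch <- sample(rep_len(seq_len(K), cfg@nSamples))
    cls <- sample.int(nC, cfg@nSamples, replace = TRUE, prob = cfg@classProportions)
    if (cfg@confounding > 0) {
      dictated <- runif(cfg@nSamples) < cfg@confounding
      cls[dictated] <- ((batch[dictated] - 1) %% nC) + 1
    }

    qcBatch <- rep(seq_len(K), each = cfg@nQCPerBatch)
    allBatch <- c(batch, qcBatch)
    allCls <- c(cls, rep(NA_integer_, length(qcBatch)))
    isQC <- c(rep(FALSE, cfg@nSamples), rep(TRUE, length(qcBatch)))
    n <- length(allBatch)

    eps <- matrix(rnorm(n * p, 0, cfg@noiseSD), n, p)
    values <- matrix(baseline, n, p, byrow = TRUE)
    notQC <- which(!isQC)
    values[notQC, ] <- values[notQC, ] + classEffect[allCls[notQC], , drop = FALSE]
    values <- (values + eps + batchLoc[allBatch, , drop = FALSE]) *
      batchScale[allBatch, , drop = FALSE]

    sampleIDs <- sprintf("s%03d", seq_len(n))
    featureIDs <- sprintf("f%03d", seq_len(p))
    dimnames(values) <- list(sampleIDs, featureIDs)
    ds <- OmicsSet(values,
                   batch = paste0("batch", allBatch),
                   cls = ifelse(is.na(allCls), NA_character_, paste0("class", allCls)),
                   isQC = isQC)
    classMeans <- sweep(classEffect[, informative, drop = FALSE], 2,
                        baseline[informative], "+")
    rownames(batchLoc) <- rownames(batchScale) <- paste0("batch", seq_len(K))
    truth <- methods::new("SyntheticGroundTruth",
                          batchLocation = batchLoc, batchScale = batchScale,
                          baseline = baseline, informativeFeatures = informative,
                          classMeans = classMeans)
    list(dataset = ds, truth = truth)
  })
}

#' Synthetic fixture mirroring the adenocarcinoma study composition
#'
#' Metadata mirrors the printed composition of the colorectal
#' adenocarcinoma metabolomics cohort: 642 samples = 568 patients (497
#' colorectal cancer, 71 chronic enteritis; the dominant class is 87.5% of
#' patients) plus 74 pooled QC injections, acquired in three batches of
#' 192/192/184 patients with 25/25/24 QCs. Feature content is synthetic
#' (the generator's batch and class effects); only the composition mirrors
#' the real study.
#'
#' @param nFeatures number of synthetic features.
#' @param seed integer seed.
#' @return an [OmicsSet-class].
#' @export
fixtureAdenocarcinomaCounts <- function(nFeatures = 100, seed = 2023) {
  patientsPerBatch <- c(192L, 192L, 184L)
  cancerPerBatch <- c(168L, 168L, 161L)   # sums to 497; enteritis 24/24/23 = 71
  qcPerBatch <- c(25L, 25L, 24L)
  batch <- integer(0); cls <- character(0); qc <- logical(0)
  for (b in 1:3) {
    nb <- patientsPerBatch[b]
    cb <- c(rep("cancer", cancerPerBatch[b]), rep("enteritis", nb - cancerPerBatch[b]))
    batch <- c(batch, rep(b, nb), rep(b, qcPerBatch[b]))
    cls <- c(cls, cb, rep(NA_character_, qcPerBatch[b]))
    qc <- c(qc, rep(FALSE, nb), rep(TRUE, qcPerBatch[b]))
  }
  simulateFromComposition(batch, cls, qc, nFeatures = nFeatures, seed = seed)
}

#' Synthetic fixture mirroring the aging-mice study composition
#'
#' Metadata mirrors the printed composition of the aging-mice peptide
#' dataset: 372 samples in 7 batches (mean 53.14 samples per batch), 171
#' high-fat-diet vs 201 chow-diet mice, no retained QC samples. Feature
#' content is synthetic.
#'
#' @inheritParams fixtureAdenocarcinomaCounts
#' @return an [OmicsSet-class].
#' @export
fixtureAgingMiceCounts <- function(nFeatures = 100, seed = 2023) {
  batchSizes <- c(20L, 30L, 40L, 50L, 60L, 77L, 95L)  # sums to 372, heterogeneous
  batch <- rep(seq_along(batchSizes), batchSizes)
  cls <- withSeed(childSeed(seed, 7L),
                  sample(c(rep("high_fat", 171L), rep("chow", 201L))))
  simulateFromComposition(batch, cls, rep(FALSE, length(batch)),
                          nFeatures = nFeatures, seed = seed)
}

# Generate intensities for an explicit batch/class/QC composition using the
# same effect structure as generateSynthetic.
simulateFromComposition <- function(batch, cls, qc, nFeatures, seed,
                                    effectSize = 1, batchShiftSD = 1,
                                    batchScaleSD = 0.05, noiseSD = 1) {
  withSeed(seed, {
    n <- length(batch)
    p <- nFeatures
    batch <- as.integer(factor(batch))
    K <- max(batch)
    clsF <- factor(cls)
    nC <- max(2L, nlevels(clsF))
    baseline <- rnorm(p, 20, 2)
    informative <- sort(sample.int(p, max(1L, round(p / 10))))
    classEffect <- matrix(0, nC, p)
    for (cc in seq_len(nC)) classEffect[cc, informative] <- (cc - 1) * effectSize
    batchLoc <- matrix(rnorm(K * p, 0, batchShiftSD), K, p)
    batchScale <- matrix(exp(rnorm(K * p, 0, batchScaleSD)), K, p)
    values <- matrix(baseline, n, p, byrow = TRUE)
    ci <- as.integer(clsF)
    nonqc <- which(!qc & !is.na(ci))
    values[nonqc, ] <- values[nonqc, ] + classEffect[ci[nonqc], , drop = FALSE]
    values <- (values + matrix(rnorm(n * p, 0, noiseSD), n, p) +
                 batchLoc[batch, , drop = FALSE]) * batchScale[batch, , drop = FALSE]
    dimnames(values) <- list(sprintf("s%04d", seq_len(n)), sprintf("f%03d", seq_len(p)))
    OmicsSet(values, batch = paste0("batch", batch), cls = cls, isQC = qc)
  })
}
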
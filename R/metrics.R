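#' k-nearest-neighbour batch membership probabilities
#'
#' For every sample, the probability of belonging to each batch is the
#' relative frequency of batch labels among its `k` nearest neighbours
#' (Euclidean distance, the sample itself excluded, distance ties broken by
#' sample index). This probe is the basis of all batch-mixing metrics: its
#' probability rows feed the normalized batch entropy, and its argmax
#' predictions feed ARI and AMI.
#'
#' @param X numeric matrix, samples x dimensions (a feature space or an
#'   autoencoder embedding).
#' @param batch per-sample batch labels (>= 2 distinct).
#' @param k neighbour count; the study default is 20.
#' @return an `n x K` matrix of probabilities with batch levels as column
#'   names; rows sum to 1.
#' @export
knnBatchProbabilities <- function(X, batch, k = 20) {
  X <- as.matrix(X)
  n <- nrow(X)
  batch <- factor(batch)
  if (length(batch) != n) stopf("batch labels (%d) do not match rows of X (%d)", length(batch), n)
  if (nlevels(batch) < 2) stopf("need at least 2 batches, got %d", nlevels(batch))
  if (k >= n) stopf("k (%d) must be smaller than the number of samples (%d)", k, n)
  if (k < 1) stopf("k must be >= 1")
  D <- as.matrix(dist(X))
  K <- nlevels(batch)
  P <- matrix(0, n, K, dimnames = list(rownames(X), levels(batch)))
  idx <- seq_len(n)
  for (i in idx) {
    others <- idx[-i]
    ord <- others[order(D[i, others], others)]
    nb <- batch[ord[seq_len(k)]]
    P[i, ] <- tabulate(nb, nbins = K) / k
  }
  P
}

#' Normalized batch entropy (nBE)
#'
#' Per-sample batch entropy is the Shannon entropy (natural log, with
#' \eqn{0 \log 0 := 0}) of the sample's k-NN batch probability vector; BE is
#' its mean over samples. Maximum entropy \eqn{\log K} is reached when every
#' batch is equally probable (perfect mixing). nBE rescales so that lower
#' means better mixing:
#' \deqn{nBE = (\log K - BE) / \log K \in [0, 1]}
#' with 0 for uniform rows and 1 for one-hot rows.
#'
#' @param P probability matrix (rows sum to 1), e.g. from
#'   [knnBatchProbabilities()].
#' @param K number of batches; defaults to `ncol(P)`.
#' @return nBE in `[0, 1]`.
#' @export
normalizedBatchEntropy <- function(P, K = ncol(P)) {
  P <- as.matrix(P)
  if (any(P < 0)) stopf("probabilities must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-6)) stopf("rows of P must sum to 1")
  if (K < 2) stopf("K must be >= 2")
  ent <- -rowSums(ifelse(P > 0, P * log(P), 0))
  (log(K) - mean(ent)) / log(K)
}

contingency <- function(a, b) {
  if (length(a) != length(b)) {
    stopf("label vectors differ in length (%d vs %d)", length(a), length(b))
  }
  table(factor(a), factor(b))
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement between two partitions, adjusted for chance:
#' identical partitions score 1 and random labelings score approximately 0.
#' Computed from the contingency table via the standard
#' \eqn{\binom{n_{ij}}{2}} sums. Returns 1 for the degenerate case where
#' the index and its expectation coincide (e.g. both partitions trivial).
#'
#' @param pred,truth equal-length label vectors.
#' @return ARI (at most 1).
#' @export
adjustedRandIndex <- function(pred, truth) {
  tab <- contingency(pred, truth)
  n <- sum(tab)
  if (n < 2) stopf("need at least 2 samples")
  choose2 <- function(x) x * (x - 1) / 2
  sumij <- sum(choose2(tab))
  suma <- sum(choose2(rowSums(tab)))
  sumb <- sum(choose2(colSums(tab)))
  expected <- suma * sumb / choose2(n)
  maxidx <- (suma + sumb) / 2
  if (abs(maxidx - expected) < .Machine$double.eps) return(1)
  (sumij - expected) / (maxidx - expected)
}

#' Adjusted mutual information between two labelings
#'
#' \deqn{AMI = \frac{MI - E[MI]}{\mathrm{mean}(H(U), H(V)) - E[MI]}}
#' where the expected mutual information under random labelings with fixed
#' marginals is the hypergeometric sum
#' \deqn{E[MI] = \sum_i \sum_j \sum_{n_{ij}} \frac{n_{ij}}{N}
#'   \log\frac{N n_{ij}}{a_i b_j} \cdot
#'   \frac{a_i! b_j! (N-a_i)! (N-b_j)!}{N! n_{ij}! (a_i-n_{ij})!
#'   (b_j-n_{ij})! (N-a_i-b_j+n_{ij})!}}
#' with \eqn{n_{ij}} ranging from \eqn{\max(1, a_i+b_j-N)} to
#' \eqn{\min(a_i, b_j)}. Identical partitions score 1; independent ones
#' approximately 0. When both partitions are a single cluster the value is
#' defined as 1 (identical-partitions convention).
#'
#' @param pred,truth equal-length label vectors.
#' @return AMI (at most 1, up to numerical round-off).
#' @export
adjustedMutualInformation <- function(pred, truth) {
  tab <- contingency(pred, truth)
  N <- sum(tab)
  if (N < 2) stopf("need at least 2 samples")
  a <- rowSums(tab)
  b <- colSums(tab)
  if (length(a) == 1 && length(b) == 1) return(1)
  mi <- mutualInformation(tab)
  hU <- shannon(a / N)
  hV <- shannon(b / N)
  emi <- expectedMutualInformation(a, b, N)
  denom <- mean(c(hU, hV)) - emi
  if (abs(denom) < 1e-15) return(1)
  as.numeric((mi - emi) / denom)
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

mutualInformation <- function(tab) {
  N <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / N) * log(N * nij / (a[i] * b[j]))
  }
  mi
}

# Hypergeometric expectation of MI under fixed marginals (log-gamma form).
expectedMutualInformation <- function(a, b, N) {
  emi <- 0
  lgN <- lgamma(N + 1)
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - N)
    hi <- min(ai, bj)
    if (hi < lo) next
    for (nij in lo:hi) {
      term <- (nij / N) * log(N * nij / (ai * bj))
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(N - ai + 1) + lgamma(N - bj + 1) -
        lgN - lgamma(nij + 1) - lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(N - ai - bj + nij + 1)
      emi <- emi + term * exp(lp)
    }
  }
  emi
}

#' Average pairwise Pearson correlation of QC samples (aPCC)
#'
#' Pooled QC samples are chemically identical, so after perfect batch
#' correction every pair should correlate perfectly (PCC = 1). Computes the
#' Pearson correlation of the feature vectors of every unordered pair of QC
#' samples and averages. Pairs where either vector has zero variance are
#' dropped from the average; an error is raised if every pair is degenerate.
#'
#' @param Xqc numeric matrix of QC samples x features (>= 2 rows).
#' @return mean pairwise PCC.
#' @export
qcAveragePCC <- function(Xqc) {
  Xqc <- as.matrix(Xqc)
  m <- nrow(Xqc)
  if (m < 2) stopf("need at least 2 QC samples, got %d", m)
  vals <- c()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (sd(Xqc[i, ]) == 0 || sd(Xqc[j, ]) == 0) next
    vals <- c(vals, cor(Xqc[i, ], Xqc[j, ]))
  }
  if (!length(vals)) stopf("all QC pairs have zero variance; aPCC undefined")
  mean(vals)
}

#' Normalized median Euclidean distance of QC samples (nMED)
#'
#' The median pairwise Euclidean distance among QC samples divided by the
#' median pairwise Euclidean distance among non-QC samples. The median (not
#' the mean) is used because it is less affected by aberrant values; the
#' normalization guards against transformations that shrink all distances
#' indiscriminately. Lower is better.
#'
#' @param Xqc QC samples x features (>= 2 rows).
#' @param Xnonqc non-QC samples x features (>= 2 rows).
#' @return nMED (>= 0).
#' @export
qcNormalizedMED <- function(Xqc, Xnonqc) {
  Xqc <- as.matrix(Xqc)
  Xnonqc <- as.matrix(Xnonqc)
  if (nrow(Xqc) < 2 || nrow(Xnonqc) < 2) {
    stopf("need >= 2 QC and >= 2 non-QC samples (got %d and %d)", nrow(Xqc), nrow(Xnonqc))
  }
  ref <- median(dist(Xnonqc))
  if (ref == 0) stopf("median non-QC distance is 0; nMED undefined")
  median(dist(Xqc)) / ref
}

#' Matthews correlation coefficient
#'
#' Balanced classification score over all confusion-matrix cells, in
#' `[-1, 1]`: 1 only for perfect predictions, 0 for constant (or otherwise
#' uninformative) predictions. Multiclass inputs use the generalized
#' covariance form, which reduces to the familiar binary closed form
#' \eqn{(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#'
#' @param yTrue,yPred equal-length label vectors.
#' @return MCC in `[-1, 1]`.
#' @export
matthewsCC <- function(yTrue, yPred) {
  if (length(yTrue) == 0) stopf("empty input")
  if (length(yTrue) != length(yPred)) {
    stopf("label vectors differ in length (%d vs %d)", length(yTrue), length(yPred))
  }
  lev <- union(levels(factor(yTrue)), levels(factor(yPred)))
  C <- table(factor(yTrue, levels = lev), factor(yPred, levels = lev))
  s <- sum(C)
  correct <- sum(diag(C))
  t_k <- rowSums(C)  # true occurrences per class
  p_k <- colSums(C)  # predicted occurrences per class
  num <- correct * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Compose the full metrics panel for one representation
#'
#' Runs the k-NN batch probe on `X` (all rows, QC included), filling `nBE`
#' from the probability rows and `ARI`/`AMI` from the argmax batch
#' predictions; fills the QC metrics iff `ds` carries QC samples, and
#' `mcc`/`accuracy` iff class predictions are supplied (QC samples are
#' excluded from classification scoring). The probe is fit on all supplied
#' samples of the evaluated representation.
#'
#' @param X representation matrix, rows aligned with the samples of `ds`.
#' @param ds the [OmicsSet-class] the representation belongs to.
#' @param yPred optional per-sample class predictions (`NA`/ignored on QC).
#' @param k probe neighbour count.
#' @param split,representation labels stored in the report.
#' @return a [MetricsReport-class].
#' @export
evaluateRepresentation <- function(X, ds, yPred = NULL, k = 20,
                                   split = "all", representation = "features") {
  X <- as.matrix(X)
  if (nrow(X) != ncol(ds)) {
    stopf("representation has %d rows but dataset has %d samples", nrow(X), ncol(ds))
  }
  batch <- droplevels(factor(batchLabels(ds)))
  if (nlevels(batch) >= 2) {
    k_use <- min(k, nrow(X) - 1L)
    P <- knnBatchProbabilities(X, batch, k = k_use)
    predBatch <- colnames(P)[max.col(P, ties.method = "first")]
    nbe <- normalizedBatchEntropy(P, K = nlevels(batch))
    ari <- adjustedRandIndex(predBatch, as.character(batch))
    ami <- adjustedMutualInformation(predBatch, as.character(batch))
  } else {
    # batch mixing is undefined within a single batch
    nbe <- ari <- ami <- NA_real_
  }

  qc <- isQC(ds)
  apcc <- nmed <- NA_real_
  if (sum(qc) >= 2 && sum(!qc) >= 2) {
    apcc <- qcAveragePCC(X[qc, , drop = FALSE])
    nmed <- qcNormalizedMED(X[qc, , drop = FALSE], X[!qc, , drop = FALSE])
  }

  mcc <- acc <- NA_real_
  if (!is.null(yPred)) {
    keep <- !qc & !is.na(classLabels(ds))
    yt <- as.character(classLabels(ds))[keep]
    yp <- as.character(yPred)[keep]
    mcc <- matthewsCC(yt, yp)
    acc <- mean(yt == yp)
  }
  methods::new("MetricsReport", nBE = nbe, ARI = ari, AMI = ami,
               aPCC = apcc, nMED = nmed, mcc = mcc, accuracy = acc,
               split = split, representation = representation)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport [%s / %s]\n", object@representation, object@split))
  cat(sprintf("  batch mixing: nBE=%.3f ARI=%.3f AMI=%.3f\n",
              object@nBE, object@ARI, object@AMI))
  if (!is.na(object@aPCC)) {
    cat(sprintf("  QC: aPCC=%.3f nMED=%.3f\n", object@aPCC, object@nMED))
  }
  if (!is.na(object@mcc)) {
    cat(sprintf("  classification: MCC=%.3f accuracy=%.3f\n", object@mcc, object@accuracy))
  }
})

#' Flatten a MetricsReport to a one-row data.frame
#'
#' @param report a [MetricsReport-class].
#' @param ... extra scalar columns (e.g. `method`, `iteration`).
#' @return a one-row `data.frame`.
#' @export
reportAsRow <- function(report, ...) {
  data.frame(...,
             split = report@split, representation = report@representation,
             nBE = report@nBE, ARI = report@ARI, AMI = report@AMI,
             aPCC = report@aPCC, nMED = report@nMED,
             mcc = report@mcc, accuracy = report@accuracy,
             stringsAsFactors = FALSE)
}
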
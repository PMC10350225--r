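#' Itemized loss components of one minibatch
#'
#' Slots `rec` (mean squared reconstruction error), `batchTerm` (the
#' batch-removal term on the scale *before* weighting by \eqn{\gamma};
#' negative for the subtractive NormAE-style variant), `kl`
#' (KL divergence to the unit-normal prior; 0 for the AE backbone),
#' `labelCE` (label-smoothed cross-entropy of the condition classifier; 0
#' in unsupervised phases) and `total`, which always satisfies
#' `total == rec + gamma * batchTerm + beta * kl + labelCE` with inactive
#' terms zeroed.
#'
#' @export
setClass("LossBreakdown", representation(
  rec = "numeric", batchTerm = "numeric", kl = "numeric",
  labelCE = "numeric", total = "numeric"))

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf("LossBreakdown: total=%.5g (rec=%.5g batch=%.5g kl=%.5g labelCE=%.5g)\n",
              object@total, object@rec, object@batchTerm, object@kl, object@labelCE))
})

#' KL divergence of a diagonal Gaussian posterior from the unit normal
#'
#' Closed form, averaged over samples:
#' \deqn{\frac{1}{n}\sum_i \frac{1}{2}\sum_d
#'   (\mu_{id}^2 + \sigma_{id}^2 - 1 - \log \sigma_{id}^2)}
#' This is the regularizer of the variational lower bound, pushing the
#' encoder's posterior toward the unit-normal prior.
#'
#' @param mu samples x dims matrix (or vector) of posterior means.
#' @param logvar matching matrix of posterior log-variances.
#' @return non-negative scalar.
#' @export
klDivergence <- function(mu, logvar) {
  mu <- rbind(mu)
  logvar <- rbind(logvar)
  if (!all(dim(mu) == dim(logvar))) stopf("mu and logvar shapes differ")
  mean(0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar))
}

sqDist <- function(A, B) rowSums((A - B)^2)

#' Inverse triplet loss
#'
#' Triplet hinge with the positive/negative roles swapped:
#' \deqn{\mathrm{mean}\ \max(\|f(A)-f(N)\|^2 - \|f(A)-f(P)\|^2 + \alpha, 0)}
#' where `P` shares the anchor's batch and `N` comes from a different
#' batch. Minimizing it pulls different-batch pairs together while pushing
#' same-batch pairs apart, which prevents the trivial collapse of all
#' embeddings onto one point. This is the only batch-removal loss of the
#' suite that is directly minimized (no gradient reversal).
#'
#' @param fA,fP,fN matrices of anchor / same-batch / different-batch
#'   embeddings, one triplet per row.
#' @param margin margin \eqn{\alpha \ge 0}.
#' @return non-negative scalar.
#' @export
invTripletLoss <- function(fA, fP, fN, margin) {
  fA <- rbind(fA); fP <- rbind(fP); fN <- rbind(fN)
  if (ncol(fA) != ncol(fP) || ncol(fA) != ncol(fN)) stopf("embedding widths differ")
  mean(pmax(sqDist(fA, fN) - sqDist(fA, fP) + margin, 0))
}

#' Reverse triplet loss (adversarial)
#'
#' The standard triplet hinge on batch groups,
#' \deqn{\mathrm{mean}\ \max(\|f(A)-f(P)\|^2 - \|f(A)-f(N)\|^2 + \alpha, 0),}
#' whose forward value is reported as-is but whose gradient reaches the
#' encoder through the gradient reversal contract (see
#' [gradientReversal()]): minimizing the printed loss downstream maximizes
#' batch confusion upstream.
#'
#' @inheritParams invTripletLoss
#' @return non-negative scalar (forward value).
#' @export
revTripletLoss <- function(fA, fP, fN, margin) {
  fA <- rbind(fA); fP <- rbind(fP); fN <- rbind(fN)
  if (ncol(fA) != ncol(fP) || ncol(fA) != ncol(fN)) stopf("embedding widths differ")
  mean(pmax(sqDist(fA, fP) - sqDist(fA, fN) + margin, 0))
}

#' Gradient reversal layer
#'
#' Identity in the forward direction; during backpropagation the gradient
#' flowing upstream is multiplied by \eqn{-\lambda}. This is what makes a
#' downstream batch classifier *adversarial*: the classifier itself is
#' trained to discriminate batches while the encoder upstream of the
#' reversal receives the negated gradient and learns batch-invariant
#' representations. `gradientReversal()` is the forward contract;
#' `grlBackward()` is the backward contract used by the training core.
#'
#' @param h any numeric tensor.
#' @param lambda reversal strength \eqn{\lambda \ge 0} (recorded for the
#'   backward pass).
#' @return `gradientReversal()`: `h` unchanged; `grlBackward()`:
#'   `-lambda * grad`.
#' @export
gradientReversal <- function(h, lambda = 1) {
  stopifnot(is.finite(lambda))
  h
}

#' @rdname gradientReversal
#' @param grad the gradient arriving from downstream.
#' @export
grlBackward <- function(grad, lambda = 1) -lambda * grad

# Label-smoothed cross-entropy of logits L against integer labels y (1-based).
# Returns loss value and gradient wrt logits (already averaged over rows).
smoothedCrossEntropy <- function(L, y, smoothing = 0) {
  n <- nrow(L)
  C <- ncol(L)
  Lst <- L - apply(L, 1, max)
  logZ <- log(rowSums(exp(Lst)))
  logP <- Lst - logZ
  Tg <- matrix(smoothing / C, n, C)
  Tg[cbind(seq_len(n), y)] <- Tg[cbind(seq_len(n), y)] + (1 - smoothing)
  loss <- -mean(rowSums(Tg * logP))
  grad <- (exp(logP) - Tg) / n
  list(loss = loss, grad = grad)
}

# Random within-minibatch triplet mining on batch labels: each anchor draws
# one same-batch positive and one different-batch negative; anchors lacking
# either are skipped. Consumes RNG.
mineTriplets <- function(batchIdx) {
  n <- length(batchIdx)
  anchors <- pos <- neg <- integer(0)
  for (i in seq_len(n)) {
    same <- which(batchIdx == batchIdx[i])
    same <- same[same != i]
    diff <- which(batchIdx != batchIdx[i])
    if (!length(same) || !length(diff)) next
    anchors <- c(anchors, i)
    pos <- c(pos, same[sample.int(length(same), 1)])
    neg <- c(neg, diff[sample.int(length(diff), 1)])
  }
  list(a = anchors, p = pos, n = neg)
}

#' Compute the itemized loss of a minibatch
#'
#' Forward-only evaluation of every active loss component under the model's
#' specification: mean-squared reconstruction error through the
#' (batch-mapping) decoder, the batch-removal term of the chosen strategy,
#' the KL term for the VAE backbone, and the label-smoothed classification
#' cross-entropy on labeled (non-QC) samples. For the NormAE-style
#' subtractive variant the adversarial term is clamped so the total can
#' never go negative. Triplet terms mine random within-minibatch triplets
#' and therefore consume RNG; seed for reproducibility.
#'
#' @param model a [DebatchModel-class].
#' @param x minibatch matrix, samples x features.
#' @param batchIds per-row batch labels or indices.
#' @param cls per-row class labels (or indices); `NA` for unlabeled/QC rows.
#' @param phase `"both"`, `"unsup"` (skip the label term) or `"sup"`
#'   (label term required: errors if no labeled row is present).
#' @param stochastic VAE reparameterization draw (defaults to deterministic).
#' @return a [LossBreakdown-class].
#' @export
totalLoss <- function(model, x, batchIds, cls = NULL,
                      phase = c("both", "unsup", "sup"), stochastic = FALSE) {
  phase <- match.arg(phase)
  x <- as.matrix(x)
  spec <- model@spec
  idx <- batchIndex(model, batchIds, nrow(x))
  enc <- encForward(model, x, training = FALSE, stochastic = stochastic)
  dec <- decForward(model, enc$Z, idx, training = FALSE)
  rec <- mean((dec$Xhat - x)^2)
  kl <- if (spec@backbone == "VAE") klDivergence(enc$mu, enc$lv) else 0

  labelCE <- 0
  if (phase != "unsup") {
    y <- classIndexVector(model, cls, nrow(x))
    labeled <- which(!is.na(y))
    if (phase == "sup" && !length(labeled)) {
      stopf("supervised phase but no labeled samples in minibatch")
    }
    if (length(labeled)) {
      Ly <- addRow(enc$Z[labeled, , drop = FALSE] %*% model@params$Wy, model@params$by)
      labelCE <- smoothedCrossEntropy(Ly, y[labeled], spec@labelSmoothing)$loss
    }
  }

  batchTerm <- 0
  if (spec@removal %in% c("DANN", "NormAE")) {
    ceB <- smoothedCrossEntropy(fbForward(model, enc$Z)$logits, idx, 0)$loss
    if (spec@removal == "DANN") {
      batchTerm <- ceB
    } else {
      other <- rec + (if (spec@backbone == "VAE") spec@beta * kl else 0) + labelCE
      batchTerm <- if (spec@gamma > 0) -min(spec@gamma * ceB, other) / spec@gamma else 0
    }
  } else if (spec@removal %in% c("invTriplet", "revTriplet")) {
    tri <- mineTriplets(idx)
    if (length(tri$a)) {
      fA <- enc$Z[tri$a, , drop = FALSE]
      fP <- enc$Z[tri$p, , drop = FALSE]
      fN <- enc$Z[tri$n, , drop = FALSE]
      batchTerm <- if (spec@removal == "invTriplet") {
        invTripletLoss(fA, fP, fN, spec@margin)
      } else {
        revTripletLoss(fA, fP, fN, spec@margin)
      }
    }
  }

  beta <- if (spec@backbone == "VAE") spec@beta else 0
  total <- rec + spec@gamma * batchTerm + beta * kl + labelCE
  methods::new("LossBreakdown", rec = rec, batchTerm = batchTerm,
               kl = if (spec@backbone == "VAE") kl else 0,
               labelCE = labelCE, total = total)
}

classIndexVector <- function(model, cls, n) {
  if (is.null(cls)) return(rep(NA_integer_, n))
  if (is.numeric(cls)) return(as.integer(cls))
  y <- match(as.character(cls), model@classLevels)
  bad <- !is.na(cls) & is.na(y)
  if (any(bad)) {
    stopf("unknown class label(s): %s", paste(unique(as.character(cls)[bad]), collapse = ", "))
  }
  y
}
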
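#' Build a model of the suite
#'
#' Architecture: input -> `layer1` -> bottleneck -> `layer2` -> output with
#' rectified-linear hidden layers, linear output, and dropout on the hidden
#' layers. The VAE backbone parameterizes the bottleneck as a diagonal
#' Gaussian (mean and log-variance heads). The batch classifier is a
#' one-hidden-layer network on the bottleneck (a nonlinear discriminator is
#' needed for the adversarial game to enforce local batch mixing rather
#' than mere linear non-separability); the condition classifier is linear
#' on the bottleneck. The batch embedding table (one learned
#' vector of bottleneck size per batch, used by the batch-mapping decoder)
#' is initialized to zeros so batch mapping is an exact no-op at
#' initialization. Weight initialization is deterministic given `seed`.
#'
#' @param spec a [ModelSpec()].
#' @param nFeatures input dimension.
#' @param K number of batches.
#' @param nClasses number of condition classes.
#' @param seed integer seed for the initialization.
#' @param batchLevels,classLevels optional label levels recorded for
#'   prediction; defaults are generic names.
#' @return a [DebatchModel-class].
#' @export
buildModel <- function(spec, nFeatures, K, nClasses, seed = 1,
                       batchLevels = paste0("batch", seq_len(K)),
                       classLevels = paste0("class", seq_len(nClasses))) {
  validObject(spec)
  nFeatures <- as.integer(nFeatures)
  K <- as.integer(K)
  nClasses <- as.integer(nClasses)
  h1 <- spec@layer1; h2 <- spec@layer2; dz <- spec@bottleneck
  he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  params <- withSeed(seed, {
    p <- list(
      W1 = he(nFeatures, h1), b1 = numeric(h1),
      W3 = he(dz, h2), b3 = numeric(h2),
      W4 = he(h2, nFeatures), b4 = numeric(nFeatures),
      Wb1 = he(dz, h2), bb1 = numeric(h2),
      Wb2 = he(h2, K), bb2 = numeric(K),
      Wy = he(dz, nClasses), by = numeric(nClasses),
      emb = matrix(0, K, dz))
    if (spec@backbone == "VAE") {
      p$W2mu <- he(h1, dz); p$b2mu <- numeric(dz)
      p$W2lv <- matrix(rnorm(h1 * dz, 0, 0.01), h1, dz); p$b2lv <- numeric(dz)
    } else {
      p$W2 <- he(h1, dz); p$b2 <- numeric(dz)
    }
    p
  })
  methods::new("DebatchModel", spec = spec, params = params,
               nFeatures = nFeatures, nBatches = K, nClasses = nClasses,
               batchLevels = as.character(batchLevels),
               classLevels = as.character(classLevels),
               seed = as.integer(seed))
}

setMethod("show", "DebatchModel", function(object) {
  cat(sprintf("DebatchModel %s: %d features, %d batches, %d classes\n",
              modelName(object@spec), object@nFeatures, object@nBatches, object@nClasses))
  cat(sprintf("  parameters: %d tensors (%d values)\n", length(object@params),
              sum(vapply(object@params, length, 1L))))
})

addRow <- function(M, v) sweep(M, 2, v, "+")
relu <- function(x) pmax(x, 0)

# Encoder forward pass with caches for backprop. `training` enables dropout
# (consumes RNG); `stochastic` draws the VAE reparameterization sample.
encForward <- function(model, X, training = FALSE, stochastic = FALSE) {
  p <- model@params
  spec <- model@spec
  H1pre <- addRow(X %*% p$W1, p$b1)
  H1 <- relu(H1pre)
  mask1 <- NULL
  if (training && spec@dropout > 0) {
    mask1 <- matrix(rbinom(length(H1), 1, 1 - spec@dropout), nrow(H1)) / (1 - spec@dropout)
    H1 <- H1 * mask1
  }
  if (spec@backbone == "VAE") {
    mu <- addRow(H1 %*% p$W2mu, p$b2mu)
    lv <- addRow(H1 %*% p$W2lv, p$b2lv)
    lv <- pmin(pmax(lv, -10), 10)  # keep exp() finite early in training
    if (stochastic) {
      eps <- matrix(rnorm(length(mu)), nrow(mu))
      Z <- mu + exp(0.5 * lv) * eps
    } else {
      eps <- matrix(0, nrow(mu), ncol(mu))
      Z <- mu
    }
    list(Z = Z, mu = mu, lv = lv, eps = eps, H1pre = H1pre, H1 = H1, mask1 = mask1, X = X)
  } else {
    Z <- addRow(H1 %*% p$W2, p$b2)
    list(Z = Z, mu = NULL, lv = NULL, eps = NULL, H1pre = H1pre, H1 = H1,
         mask1 = mask1, X = X)
  }
}

# Decoder forward pass. batchIdx: integer batch index per row (for the
# batch-mapping embedding), or NULL to skip mapping.
decForward <- function(model, Z, batchIdx = NULL, training = FALSE) {
  p <- model@params
  spec <- model@spec
  Zin <- Z
  if (spec@useBatchMapping && !is.null(batchIdx)) {
    Zin <- Z + p$emb[batchIdx, , drop = FALSE]
  }
  H2pre <- addRow(Zin %*% p$W3, p$b3)
  H2 <- relu(H2pre)
  mask2 <- NULL
  if (training && spec@dropout > 0) {
    mask2 <- matrix(rbinom(length(H2), 1, 1 - spec@dropout), nrow(H2)) / (1 - spec@dropout)
    H2 <- H2 * mask2
  }
  Xhat <- addRow(H2 %*% p$W4, p$b4)
  list(Xhat = Xhat, H2pre = H2pre, H2 = H2, mask2 = mask2, Zin = Zin, batchIdx = batchIdx)
}

# Batch classifier forward pass (one hidden relu layer) with caches.
fbForward <- function(model, Z) {
  p <- model@params
  Hpre <- addRow(Z %*% p$Wb1, p$bb1)
  H <- relu(Hpre)
  list(logits = addRow(H %*% p$Wb2, p$bb2), H = H, Hpre = Hpre)
}

softmaxRows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Encode samples to the bottleneck representation
#'
#' @param model a [DebatchModel-class].
#' @param x samples x features matrix (width must match the model).
#' @param stochastic VAE only: draw one reparameterization sample
#'   \eqn{z = \mu + \sigma \odot \epsilon}; otherwise \eqn{z = \mu}.
#'   Seed the R RNG for reproducible draws.
#' @return a list with `z` (samples x bottleneck) and, for the VAE backbone,
#'   `mu` and `logvar`.
#' @export
encode <- function(model, x, stochastic = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != model@nFeatures) {
    stopf("input has %d features but the model expects %d", ncol(x), model@nFeatures)
  }
  fw <- encForward(model, x, training = FALSE, stochastic = stochastic)
  if (model@spec@backbone == "VAE") list(z = fw$Z, mu = fw$mu, logvar = fw$lv)
  else list(z = fw$Z)
}

#' Decode bottleneck vectors to reconstructed intensities
#'
#' With batch mapping enabled the learned batch-ID embedding is added to `z`
#' before decoding, so the reconstruction can re-inject batch character that
#' the embedding itself need not carry.
#'
#' @param model a [DebatchModel-class].
#' @param z samples x bottleneck matrix.
#' @param batchIds per-row batch labels (levels known to the model) or
#'   1-based integer indices; ignored when the spec disables batch mapping.
#' @return samples x features reconstruction matrix.
#' @export
decode <- function(model, z, batchIds = NULL) {
  z <- as.matrix(z)
  if (ncol(z) != model@spec@bottleneck) {
    stopf("z has width %d but bottleneck is %d", ncol(z), model@spec@bottleneck)
  }
  idx <- NULL
  if (model@spec@useBatchMapping) {
    if (is.null(batchIds)) stopf("batchIds required when batch mapping is enabled")
    idx <- batchIndex(model, batchIds, nrow(z))
  }
  decForward(model, z, idx, training = FALSE)$Xhat
}

batchIndex <- function(model, batchIds, n) {
  if (is.numeric(batchIds)) {
    idx <- as.integer(batchIds)
    if (any(idx < 1 | idx > model@nBatches)) stopf("batch index out of range 1..%d", model@nBatches)
  } else {
    idx <- match(as.character(batchIds), model@batchLevels)
    if (any(is.na(idx))) {
      stopf("unknown batch id(s): %s",
            paste(unique(as.character(batchIds)[is.na(idx)]), collapse = ", "))
    }
  }
  if (length(idx) == 1) idx <- rep(idx, n)
  if (length(idx) != n) stopf("batchIds length %d does not match %d rows", length(idx), n)
  idx
}

#' Class logits and predictions from a trained model
#'
#' Encodes deterministically (VAE: \eqn{z = \mu}) and applies the condition
#' classifier head.
#'
#' @param model a [DebatchModel-class].
#' @param x samples x features matrix.
#' @return `predictLogits`: samples x classes logit matrix;
#'   `predictClasses`: factor of predicted class labels.
#' @export
predictLogits <- function(model, x) {
  z <- encode(model, x)$z
  addRow(z %*% model@params$Wy, model@params$by)
}

#' @rdname predictLogits
#' @export
predictClasses <- function(model, x) {
  L <- predictLogits(model, x)
  factor(model@classLevels[max.col(L, ties.method = "first")], levels = model@classLevels)
}
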
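#' Construct a model specification
#'
#' @param backbone `"AE"` (deterministic) or `"VAE"` (variational).
#' @param removal batch-removal strategy: `"none"`, `"DANN"` (adversarial
#'   batch classifier trained through a gradient reversal layer),
#'   `"NormAE"` (adversarial batch classifier without gradient reversal,
#'   its cross-entropy subtracted from the loss with a non-negativity
#'   guard), `"invTriplet"` (inverse triplet loss: different-batch pairs
#'   pulled together, same-batch pairs pushed apart) or `"revTriplet"`
#'   (standard triplet loss on batch groups routed through gradient
#'   reversal).
#' @param layer1,layer2 hidden widths before and after the bottleneck.
#' @param bottleneck embedding dimension.
#' @param dropout dropout probability on hidden layers.
#' @param margin triplet margin \eqn{\alpha}; required for the triplet removals.
#' @param beta KL weight \eqn{\beta} (VAE only).
#' @param gamma batch-removal loss weight \eqn{\gamma} (also the gradient
#'   reversal strength).
#' @param labelSmoothing label smoothing of the condition classifier.
#' @param useBatchMapping add a learned batch-ID embedding to the bottleneck
#'   before decoding, so the bottleneck itself need not encode batch.
#' @param zReg L2 activity regularization of the embedding (AE backbone
#'   only), applied optimizer-side during unsupervised passes.
#' @return a [ModelSpec-class].
#' @export
ModelSpec <- function(backbone = c("AE", "VAE"),
                      removal = c("none", "DANN", "NormAE", "invTriplet", "revTriplet"),
                      layer1 = 64, layer2 = 64, bottleneck = 32, dropout = 0.3,
                      margin = NA_real_, beta = NA_real_, gamma = 1,
                      labelSmoothing = 0, useBatchMapping = TRUE, zReg = 0.01) {
  backbone <- match.arg(backbone)
  removal <- match.arg(removal)
  if (backbone == "VAE" && is.na(beta)) beta <- 1
  methods::new("ModelSpec",
               backbone = backbone, removal = removal,
               layer1 = as.integer(layer1), layer2 = as.integer(layer2),
               bottleneck = as.integer(bottleneck), dropout = as.numeric(dropout),
               margin = as.numeric(margin), beta = as.numeric(beta),
               gamma = as.numeric(gamma), labelSmoothing = as.numeric(labelSmoothing),
               useBatchMapping = isTRUE(useBatchMapping), zReg = as.numeric(zReg))
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s\n", modelName(object)))
  cat(sprintf("  layers %d -> %d -> %d, dropout %.2f, batch mapping: %s\n",
              object@layer1, object@bottleneck, object@layer2, object@dropout,
              object@useBatchMapping))
  cat(sprintf("  gamma=%.3g", object@gamma))
  if (!is.na(object@margin)) cat(sprintf(" margin=%.3g", object@margin))
  if (!is.na(object@beta)) cat(sprintf(" beta=%.3g", object@beta))
  cat(sprintf(" labelSmoothing=%.3g\n", object@labelSmoothing))
})

#' Canonical identifier of a grid cell, e.g. "AE-DANN"
#'
#' @param spec a [ModelSpec-class].
#' @return character scalar.
#' @export
modelName <- function(spec) paste(spec@backbone, spec@removal, sep = "-")

#' Enumerate the full model grid
#'
#' The two backbones crossed with the five batch-removal strategies give
#' exactly ten distinct models.
#'
#' @param ... common hyperparameters forwarded to [ModelSpec()]; a margin
#'   default of 1 is supplied for the triplet removals.
#' @return named list of ten [ModelSpec-class] objects.
#' @export
modelGrid <- function(...) {
  args <- list(...)
  specs <- list()
  for (backbone in c("AE", "VAE")) {
    for (removal in c("none", "DANN", "NormAE", "invTriplet", "revTriplet")) {
      a <- args
      a$backbone <- backbone
      a$removal <- removal
      if (removal %in% c("invTriplet", "revTriplet") && is.null(a$margin)) a$margin <- 1
      spec <- do.call(ModelSpec, a)
      specs[[modelName(spec)]] <- spec
    }
  }
  specs
}
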
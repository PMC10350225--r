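# Small datasets built in code for the unit tests.

# A tiny two-batch dataset with hand-set values.
toyOmicsSet <- function() {
  values <- matrix(c(1, 2,
                     3, 4,
                     5, 6,
                     7, 8), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), c("fA", "fB")))
  OmicsSet(values, batch = c("b1", "b1", "b2", "b2"),
           cls = c("A", "B", "A", "B"))
}

# Linearly separable two-class data in a 3+ batch layout, for training
# smoke tests: class signal on the first features, tiny noise.
separableDataset <- function(n = 90, p = 10, nBatches = 3, seed = 11,
                             effect = 4, noise = 0.3) {
  withr::with_seed(seed, {
    cls <- rep(1:2, length.out = n)
    batch <- rep(seq_len(nBatches), length.out = n)
    X <- matrix(rnorm(n * p, 0, noise), n, p)
    X[, 1:3] <- X[, 1:3] + effect * (cls - 1)
    dimnames(X) <- list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p))
    OmicsSet(X, batch = paste0("b", batch), cls = paste0("c", cls))
  })
}

smallSpec <- function(backbone = "AE", removal = "none", ...) {
  args <- list(backbone = backbone, removal = removal,
               layer1 = 16, layer2 = 16, bottleneck = 4, dropout = 0)
  if (removal %in% c("invTriplet", "revTriplet")) args$margin <- 1
  do.call(ModelSpec, modifyList(args, list(...)))
}

fastConfig <- function(...) {
  args <- modifyList(
    list(scenario = "alternating", warmupEpochs = 3, maxEpochs = 8,
         patience = 8, batchSize = 32, learningRate = 2e-3, seed = 99),
    list(...))
  args$patience <- min(args$patience, args$maxEpochs)
  do.call(TrainConfig, args)
}
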
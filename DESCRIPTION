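Package: debatch
Title: Adversarial Autoencoders for Batch Effect Correction in Multi-Batch LC-MS Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A suite of autoencoder-based neural models that remove batch
    effects from multi-batch liquid chromatography mass spectrometry (LC-MS)
    proteomics and metabolomics intensity tables while maximizing sample
    classification performance on batches never seen during training. Provides
    two backbones (deterministic and variational autoencoders) crossed with
    five batch-removal strategies (none, domain-adversarial training via a
    gradient reversal layer, a subtractive adversarial variant without
    gradient reversal, and inverse/reverse triplet losses on batch groups),
    batch-mapping decoders, a two-scenario training protocol with batch-wise
    repetitive holdout, batch-mixing metrics (normalized batch entropy,
    adjusted Rand index, adjusted mutual information via a k-nearest-neighbour
    batch probe), quality-control replicate metrics (average pairwise Pearson
    correlation and normalized median Euclidean distance), Matthews
    correlation for imbalanced classification, classical baseline classifiers,
    additive feature attributions for trained models, and a synthetic
    multi-batch data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
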
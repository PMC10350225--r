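---
title: "Adversarial autoencoders for batch-effect correction in LC-MS omics"
author: "debatch package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial autoencoders for batch-effect correction in LC-MS omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debatch)
```

## The problem

Large LC-MS proteomics and metabolomics studies are acquired in batches,
and each batch imprints systematic, analyte-specific distortions on the
quantified intensities: additive location shifts and multiplicative scale
changes on the log scale. Left uncorrected, a classifier trained on some
batches fails on new ones; corrected too aggressively, the biological
signal goes with the batch signal. `debatch` implements a suite of
autoencoder models that remove batch structure from a learned embedding
while *maximizing classification performance on batches never seen during
training*, together with the metrics needed to judge both sides of that
trade-off and a synthetic generator that makes the whole pipeline testable
without external data.

## The model grid

Every model is an autoencoder: an encoder maps the `p` log intensities to
a bottleneck embedding `z` (input → `layer1` → bottleneck, rectified
hidden units, dropout), and a decoder mirrors it back. Two backbones exist:

* **AE** — deterministic bottleneck;
* **VAE** — the bottleneck is a diagonal Gaussian `N(mu(x), sigma(x)^2)`;
  one reparameterized sample `z = mu + sigma * eps` feeds the decoder and
  both classifiers, and the KL divergence to the unit-normal prior,
  `mean(0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2))`, is added with
  weight `beta`.

A linear condition classifier and a one-hidden-layer batch classifier read
the bottleneck. When `useBatchMapping` is on, a learned per-batch vector is
added to `z` before decoding, so the reconstruction — which genuinely needs
batch information — can obtain it without the embedding having to carry it.
The batch-embedding table starts at zero, making batch mapping an exact
no-op at initialization.

Crossing the two backbones with five batch-removal strategies gives the
ten-model grid (`modelGrid()`):

| removal | mechanism |
|---|---|
| `none` | plain autoencoder |
| `DANN` | batch classifier made adversarial through gradient reversal |
| `NormAE` | adversarial batch classifier without gradient reversal; its cross-entropy is subtracted, with a clamp so the total loss cannot go negative |
| `invTriplet` | inverse triplet loss: different-batch pairs pulled together, same-batch pairs pushed apart (prevents collapse); the only batch-removal loss that is directly minimized |
| `revTriplet` | standard triplet loss on batch groups, routed through gradient reversal |

The per-minibatch loss is always
`total = rec + gamma * batchTerm + beta * kl + labelCE`, with inactive
terms zeroed; `rec` is the mean squared reconstruction error and `labelCE`
the label-smoothed cross-entropy of the condition classifier on labeled
(non-QC) samples.

## Making the adversarial game actually mix batches

Three numerical choices matter here, and they were genuinely open:

1. **Non-saturating adversarial direction.** The textbook reversal —
   encoder receives `-lambda` times the gradient of the discrimination
   cross-entropy — has two failure modes we observed directly: once the
   batch head is confident its softmax gradient vanishes and the game
   stalls with batches still separable; before that, ascending the
   cross-entropy is unbounded and inflates the embedding rather than
   mixing it. The training core therefore keeps the head minimizing the
   true discrimination cross-entropy while the encoder descends the
   cross-entropy against the *uniform* batch target (logit gradient
   `softmax - 1/K`). Both couplings share the same fixed point — uniform
   batch posterior, discrimination loss at its random-classification
   plateau `log K` — but the confusion direction never vanishes. The
   gradient-reversal operator itself (`gradientReversal()` /
   `grlBackward()`) is exposed and honored exactly (forward identity,
   backward `-lambda * grad`); `revTriplet` uses it, with its reversed
   push saturating once the triplet loss reaches the margin (the
   mixed-state plateau).
2. **A compact arena.** An unbounded latent lets the encoder outrun any
   discriminator. The VAE's KL term bounds the embedding by construction;
   for the AE backbone a small L2 activity regularizer on the embedding
   (`zReg`, default 0.01, applied optimizer-side like weight decay) plays
   the same role. With it, AE-DANN takes the batch entropy of a strongly
   batch-confounded synthetic set from 1.0 to below 0.1 under purely
   unsupervised training.
3. **A near-optimal discriminator.** The batch head gets three extra
   head-only updates per minibatch. Only against a near-optimal head does
   holding the plateau force genuine neighborhood-level mixing instead of
   a lagging pursuit; and only a *nonlinear* head (one hidden layer) can
   demand more than linear non-separability, which is why the
   k-nearest-neighbour mixing metrics respond to it.

## Training protocol

Both scenarios begin with a **warmup** (step 1) that trains every
unsupervised component — reconstruction, KL, batch removal — on the whole
dataset, validation and test batches and QC samples included; class labels
are never read. Afterwards:

* **frozen** — the autoencoder is frozen and only the condition classifier
  trains on the training batches;
* **alternating** — epochs alternate one full unsupervised pass (all
  samples) with one full supervised pass (training batches, gradients
  flowing through the encoder).

Supervised minibatches are drawn with weights inversely proportional to
class frequencies (`classWeights()`), so minority-class samples are seen
as often as majority ones. Validation MCC is computed after every epoch;
early stopping keeps the parameters of the best epoch (ties keep the
earlier epoch) with defaults patience 100 within a 1000-epoch cap and
minibatch size 32. The optimizer is Adam with L2 weight decay; learning
rate, weight decay, dropout, warmup length, layer widths, label smoothing,
margin, `beta` and `gamma` are the searchable hyperparameters
(`hyperparameterSearch()`, seeded random search over `budget`
configurations — the strategy is declared in its result — selecting by
mean validation MCC only; test MCC is recorded but never drives
selection).

Because generalization to *new batches* is the declared objective, splits
are drawn at batch level: every batch lies wholly inside train, valid or
test, and the test set is resampled at every holdout iteration
(`makeHoldoutSplits()`). Repeat-visit subjects stay intact automatically
since their samples share a batch. With the minimum of three batches each
split holds exactly one batch; batch-mixing metrics are then undefined
within a split and reported as `NA` there, while full-data metrics remain
available.

## Metrics

All batch-mixing metrics derive from a k-nearest-neighbour batch probe
(k = 20, Euclidean distance, self excluded, distance ties broken by sample
index): each sample's row of batch probabilities is the relative frequency
of batch labels among its neighbours.

* **nBE** — per-sample Shannon entropy (natural log, `0 log 0 = 0`) of
  the probability rows, averaged, then rescaled as
  `(log K - BE) / log K`: 0 means perfect mixing (uniform rows), 1 perfect
  separation (one-hot rows). The full probability vector is used rather
  than a single surprisal, which would be undefined at zero probabilities.
* **ARI / AMI** — chance-adjusted agreement between the probe's argmax
  predictions and the true batches. AMI's expected-MI term is the exact
  hypergeometric sum (log-gamma arithmetic); both are validated in the
  tests against brute-force oracles (pair counting; factorial summation
  and permutation enumeration) on all small partitions. Degenerate
  single-cluster cases return 1 by the identical-partitions convention.
* **aPCC / nMED** — QC replicates are pooled aliquots, chemically
  identical by construction, so their pairwise Pearson correlation should
  be 1 and their spread small: nMED is the median pairwise Euclidean
  distance among QCs divided by the same median among biological samples
  (medians, being robust to aberrant values). Zero-variance QC pairs are
  dropped from the aPCC average; it errors only if every pair is
  degenerate.
* **MCC / accuracy** — classification quality on non-QC samples; MCC uses
  the generalized covariance form, which reduces to the familiar binary
  closed form and is 0 for constant predictions.

Metrics are computed on whatever representation is supplied: the feature
space for raw/normalized baselines, the bottleneck embedding for the
neural models. The probe is fit on all samples of the evaluated set, and
this is recorded in the report (`representation`, `split`).

## The synthetic generator

`generateSynthetic()` builds log-intensity tables as
`y = (baseline + classEffect + noise + batchLocation) * batchScale` with
per-batch, per-feature location shifts `N(0, batchShiftSD^2)` and scale
factors `exp(N(0, batchScaleSD^2))` — batch effects are analyte-specific,
as in real LC-MS drift, which makes per-batch standardization a
non-trivially good baseline. A fixed subset of features carries a class
effect (`effectSize` log units); class assignment is independent of batch
by default, with a `confounding` knob to correlate them for stress tests.
QC samples are replicates of the fixed baseline profile subjected to the
same batch effects and fresh noise, so QC ground truth is exact. The
defaults (300 samples, 200 features, 3 batches, balanced classes, 10%
informative features at one log unit, unit noise, shift SD 1, scale SD
0.05, 2 QCs per batch) describe a moderate three-batch study; the test
suite's strong-batch preset raises the shift SD to 3 (three times the
residual noise). Everything is bit-reproducible given the seed.

What the generator does *not* emulate: retention-time drift, missing
values, peptide-to-protein rollup, non-Gaussian tails, and
subject-level correlation structure. Passing tests on synthetic data
therefore demonstrate that the mechanisms work as specified — not that any
particular real dataset will reach a given score.

Two composition fixtures mirror printed study designs with synthetic
feature content: a three-batch adenocarcinoma-like cohort (642 samples =
568 patients, 87.5% dominant class, 74 QCs split 25/25/24) and a
seven-batch aging-mice-like cohort (372 samples, 171 vs 201, no QCs).

## Problem sizes used by the test suite

The acceptance-style tests train on the 300 x 200, three-batch preset with
warmup 30, at most 150 post-warmup epochs and patience 50 — large enough
for the mechanisms to express themselves, small enough to keep the suite
fast. The same reasoning fixed dropout's default at 0.3: with roughly 100
supervised training samples the networks otherwise reach a train MCC of
1.0 while generalization lags badly, and dropout is the protocol's
designated capacity control. The full protocol defaults (1000 epochs,
patience 100) remain the package defaults for real analyses.

## Degenerate inputs and conventions

* Zero-variance (or zero-IQR/zero-range) features within a normalization
  fit group are centered only, mapping to 0 — no division by zero.
* Matrix orientation is samples x features everywhere in the API and file
  I/O; the loader transposes only when told to (internally the
  `SummarizedExperiment` stores features x samples per Bioconductor
  convention).
* QC samples carry `NA` condition labels, are excluded from supervised
  losses and MCC, but participate in warmup and in the QC metrics.
* Singleton batches make per-batch z-scoring a precondition error rather
  than silently producing zeros.
* The NormAE-style subtractive loss is clamped so the total never goes
  negative (the adversarial term can otherwise dominate).
* Both training scenarios are exposed and none is silently the default
  for a dataset; warmup is re-run per holdout iteration so every
  iteration is independently reproducible from its seed.

## Known limitations

The reconstruction-based "corrected features" export
(`correctedFeatures()`) is provided for interoperability but not
recommended for downstream analysis — the decoder cannot improve on the
bottleneck, and reconstruction is only one of several competing losses.
Prefer the embedding plus `featureAttribution()` (expected-gradients
attributions satisfying per-sample completeness) for biomarker work.
Adversarial training remains a two-player game: the stabilizations above
make it reliable at the tested scales, but very small minibatches or
extreme `gamma` can still unbalance it, and the hyperparameter search is
the intended remedy, exactly as in the protocol.
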
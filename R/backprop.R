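# Hand-written reverse-mode gradients for the autoencoder suite.
#
# Two passes exist, mirroring the training protocol:
#   * unsupervised ("unsup"): reconstruction (+ KL for the VAE backbone)
#     plus the batch-removal term; updates encoder, decoder, batch embedding
#     table and (for the adversarial removals) the batch classifier head.
#     The gradient reversal contract is applied where the removal demands
#     it: the batch head itself is trained to discriminate batches while
#     the encoder receives the negated, gamma-scaled gradient.
#   * supervised ("sup"): label-smoothed cross-entropy of the condition
#     classifier on labeled rows; updates the label head and, when
#     `flowEncoder`, the encoder.
#
# All passes consume RNG (dropout, VAE sampling, triplet mining); callers
# wrap epochs in withSeed() for determinism.

computeGrads <- function(model, x, idx, y = NULL,
                         pass = c("unsup", "sup"), flowEncoder = TRUE,
                         training = TRUE) {
  pass <- match.arg(pass)
  p <- model@params
  spec <- model@spec
  n <- nrow(x)
  grads <- list()
  addGrad <- function(nm, g) grads[[nm]] <<- if (is.null(grads[[nm]])) g else grads[[nm]] + g

  stochastic <- training && spec@backbone == "VAE"
  enc <- encForward(model, x, training = training, stochastic = stochastic)
  Z <- enc$Z
  dZ <- matrix(0, n, ncol(Z))
  losses <- list(rec = 0, batchTerm = 0, kl = 0, labelCE = 0)

  if (pass == "unsup") {
    dec <- decForward(model, Z, idx, training = training)
    losses$rec <- mean((dec$Xhat - x)^2)
    dXhat <- 2 * (dec$Xhat - x) / length(x)
    addGrad("W4", crossprod(dec$H2, dXhat))
    addGrad("b4", colSums(dXhat))
    dH2 <- dXhat %*% t(p$W4)
    if (!is.null(dec$mask2)) dH2 <- dH2 * dec$mask2
    dH2pre <- dH2 * (dec$H2pre > 0)
    addGrad("W3", crossprod(dec$Zin, dH2pre))
    addGrad("b3", colSums(dH2pre))
    dZin <- dH2pre %*% t(p$W3)
    if (spec@useBatchMapping) {
      dEmb <- matrix(0, model@nBatches, ncol(Z))
      acc <- rowsum(dZin, group = idx)
      dEmb[as.integer(rownames(acc)), ] <- acc
      addGrad("emb", dEmb)
    }
    dZ <- dZ + dZin

    if (spec@backbone == "VAE") {
      losses$kl <- klDivergence(enc$mu, enc$lv)
    } else if (spec@zReg > 0) {
      # optimizer-side L2 activity regularization of the embedding (the AE
      # counterpart of the VAE's KL prior); not part of the reported loss,
      # like weight decay
      dZ <- dZ + 2 * spec@zReg * Z / n
    }

    if (spec@removal %in% c("DANN", "NormAE") && spec@gamma > 0) {
      fb <- fbForward(model, Z)
      ceB <- smoothedCrossEntropy(fb$logits, idx, 0)
      losses$batchTerm <- ceB$loss
      # The head minimizes its discrimination cross-entropy (weight gamma).
      dHb <- ceB$grad %*% t(p$Wb2)
      dHbpre <- dHb * (fb$Hpre > 0)
      addGrad("Wb2", spec@gamma * crossprod(fb$H, ceB$grad))
      addGrad("bb2", spec@gamma * colSums(ceB$grad))
      addGrad("Wb1", spec@gamma * crossprod(Z, dHbpre))
      addGrad("bb1", spec@gamma * colSums(dHbpre))
      # Encoder-side adversarial pressure, non-saturating form: descend the
      # cross-entropy against the *uniform* batch target (gradient
      # softmax - 1/K at the logits). The naive reversed gradient of the
      # true-label cross-entropy vanishes once the head is confident,
      # stalling the game before batches mix; the confusion direction keeps
      # pushing each sample toward the other batches until the head's
      # discrimination loss sits at its random plateau log K, and shares
      # its fixed point (uniform batch posterior) with the reversed form.
      n_mb <- nrow(Z)
      K <- model@nBatches
      probs <- exp(fb$logits - apply(fb$logits, 1, max))
      probs <- probs / rowSums(probs)
      gradConf <- (probs - 1 / K) / n_mb
      dHbC <- gradConf %*% t(p$Wb2)
      dHbCpre <- dHbC * (fb$Hpre > 0)
      dZ <- dZ + spec@gamma * (dHbCpre %*% t(p$Wb1))
    } else if (spec@removal %in% c("invTriplet", "revTriplet") && spec@gamma > 0) {
      tri <- mineTriplets(idx)
      if (length(tri$a)) {
        fA <- Z[tri$a, , drop = FALSE]
        fP <- Z[tri$p, , drop = FALSE]
        fN <- Z[tri$n, , drop = FALSE]
        Tn <- length(tri$a)
        if (spec@removal == "invTriplet") {
          hinge <- sqDist(fA, fN) - sqDist(fA, fP) + spec@margin
          active <- hinge > 0
          losses$batchTerm <- mean(pmax(hinge, 0))
          if (any(active)) {
            w <- spec@gamma / Tn
            dA <- 2 * (fP - fN) * w
            dP <- 2 * (fA - fP) * w
            dN <- -2 * (fA - fN) * w
            dA[!active, ] <- 0; dP[!active, ] <- 0; dN[!active, ] <- 0
            dZ <- dZ + scatterRows(dA, tri$a, n) + scatterRows(dP, tri$p, n) +
              scatterRows(dN, tri$n, n)
          }
        } else {
          hinge <- sqDist(fA, fP) - sqDist(fA, fN) + spec@margin
          active <- hinge > 0
          losses$batchTerm <- mean(pmax(hinge, 0))
          # The reversed push saturates at the mixed-state plateau: once the
          # loss reaches the margin (same-batch pairs as far apart as
          # different-batch ones) further ascent would only inflate the
          # embedding scale, not improve mixing.
          if (any(active) && losses$batchTerm < spec@margin) {
            dA <- 2 * (fN - fP) / Tn
            dP <- 2 * (fP - fA) / Tn
            dN <- 2 * (fA - fN) / Tn
            dA[!active, ] <- 0; dP[!active, ] <- 0; dN[!active, ] <- 0
            dTrip <- scatterRows(dA, tri$a, n) + scatterRows(dP, tri$p, n) +
              scatterRows(dN, tri$n, n)
            dZ <- dZ + grlBackward(dTrip, spec@gamma)
          }
        }
      }
    }
  } else {
    labeled <- which(!is.na(y))
    if (!length(labeled)) stopf("supervised pass but no labeled samples in minibatch")
    Zl <- Z[labeled, , drop = FALSE]
    Ly <- addRow(Zl %*% p$Wy, p$by)
    ce <- smoothedCrossEntropy(Ly, y[labeled], spec@labelSmoothing)
    losses$labelCE <- ce$loss
    addGrad("Wy", crossprod(Zl, ce$grad))
    addGrad("by", colSums(ce$grad))
    if (flowEncoder) {
      dZl <- ce$grad %*% t(p$Wy)
      dZ <- dZ + scatterRows(dZl, labeled, n)
    }
  }

  # Encoder backward (skipped entirely for the frozen supervised pass).
  if (pass == "unsup" || flowEncoder) {
    if (spec@backbone == "VAE") {
      dmu <- dZ
      dlv <- dZ * enc$eps * 0.5 * exp(0.5 * enc$lv)
      if (pass == "unsup" && spec@beta > 0) {
        dmu <- dmu + spec@beta * enc$mu / n
        dlv <- dlv + spec@beta * 0.5 * (exp(enc$lv) - 1) / n
      }
      addGrad("W2mu", crossprod(enc$H1, dmu))
      addGrad("b2mu", colSums(dmu))
      addGrad("W2lv", crossprod(enc$H1, dlv))
      addGrad("b2lv", colSums(dlv))
      dH1 <- dmu %*% t(p$W2mu) + dlv %*% t(p$W2lv)
    } else {
      addGrad("W2", crossprod(enc$H1, dZ))
      addGrad("b2", colSums(dZ))
      dH1 <- dZ %*% t(p$W2)
    }
    if (!is.null(enc$mask1)) dH1 <- dH1 * enc$mask1
    dH1pre <- dH1 * (enc$H1pre > 0)
    addGrad("W1", crossprod(x, dH1pre))
    addGrad("b1", colSums(dH1pre))
  }

  list(losses = losses, grads = grads)
}

# Gradients of the batch-classifier head alone (encoder frozen), used to
# keep the adversary near-optimal between joint steps.
headGrads <- function(model, x, idx, training = TRUE) {
  spec <- model@spec
  stochastic <- training && spec@backbone == "VAE"
  enc <- encForward(model, x, training = training, stochastic = stochastic)
  fb <- fbForward(model, enc$Z)
  ceB <- smoothedCrossEntropy(fb$logits, idx, 0)
  dHb <- ceB$grad %*% t(model@params$Wb2)
  dHbpre <- dHb * (fb$Hpre > 0)
  list(loss = ceB$loss, grads = list(
    Wb2 = crossprod(fb$H, ceB$grad), bb2 = colSums(ceB$grad),
    Wb1 = crossprod(enc$Z, dHbpre), bb1 = colSums(dHbpre)))
}

scatterRows <- function(G, rows, n) {
  out <- matrix(0, n, ncol(G))
  acc <- rowsum(G, group = rows)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

# ---- Adam optimizer (first-order adaptive moments, L2 weight decay) ----

adamInit <- function() list(m = list(), v = list(), t = 0L)

adamStep <- function(params, grads, state, lr, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] + weightDecay * params[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
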
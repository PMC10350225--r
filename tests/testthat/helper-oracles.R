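# Independent oracles used to cross-check the package implementations.

# Brute-force k-NN batch probabilities: all-pairs distances, explicit loop,
# ties by index order.
bruteKnnProbs <- function(X, batch, k) {
  n <- nrow(X)
  batch <- factor(batch)
  P <- matrix(0, n, nlevels(batch))
  colnames(P) <- levels(batch)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j != i) d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
    nb <- order(d, seq_len(n))[seq_len(k)]
    for (j in nb) P[i, as.integer(batch[j])] <- P[i, as.integer(batch[j])] + 1 / k
  }
  P
}

# Pair-counting adjusted Rand index: enumerate all unordered sample pairs.
pairCountARI <- function(pred, truth) {
  n <- length(pred)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- pred[i] == pred[j]
      st <- truth[i] == truth[j]
      if (sp && st) n11 <- n11 + 1
      else if (!sp && !st) n00 <- n00 + 1
      else if (sp && !st) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) 1 else num / den
}

# Naive AMI via exact factorials (valid for small n): direct summation of
# the hypergeometric expected-MI formula, arithmetic independent of the
# package's log-gamma implementation.
naiveAMI <- function(pred, truth) {
  tab <- table(factor(pred), factor(truth))
  N <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  if (length(a) == 1 && length(b) == 1) return(1)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / N) * log(N * nij / (a[i] * b[j]))
  }
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    for (nij in max(1, a[i] + b[j] - N):min(a[i], b[j])) {
      if (nij < max(1, a[i] + b[j] - N)) next
      pr <- (factorial(a[i]) * factorial(b[j]) * factorial(N - a[i]) * factorial(N - b[j])) /
        (factorial(N) * factorial(nij) * factorial(a[i] - nij) *
           factorial(b[j] - nij) * factorial(N - a[i] - b[j] + nij))
      emi <- emi + (nij / N) * log(N * nij / (a[i] * b[j])) * pr
    }
  }
  denom <- mean(c(H(a / N), H(b / N))) - emi
  if (abs(denom) < 1e-15) return(1)
  as.numeric((mi - emi) / denom)
}

# Exact expected MI by exhaustive enumeration of all permutations of one
# labeling (the definition of the fixed-marginals null), n <= 7.
allPerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in allPerms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

permutationEMI <- function(pred, truth) {
  miOf <- function(p, t) {
    tab <- table(factor(p), factor(t))
    N <- sum(tab)
    a <- rowSums(tab); b <- colSums(tab)
    mi <- 0
    for (i in seq_along(a)) for (j in seq_along(b)) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + (nij / N) * log(N * nij / (a[i] * b[j]))
    }
    mi
  }
  mean(vapply(allPerms(pred), miOf, numeric(1), t = truth))
}

# All partitions of n items into at most maxGroups groups, as restricted
# growth strings.
allPartitions <- function(n, maxGroups) {
  out <- list()
  recurse <- function(prefix, used) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (g in seq_len(min(used + 1, maxGroups))) {
      recurse(c(prefix, g), max(used, g))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Central finite-difference derivative of a scalar function.
numDeriv <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)
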
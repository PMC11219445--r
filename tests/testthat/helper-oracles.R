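# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Two-sided Fisher p by explicit enumeration over the hypergeometric
# support, with table probabilities built from a recursive odds ratio
# rather than dhyper.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  logp <- numeric(length(support))
  logp[1L] <- lchoose(m, lo) + lchoose(n, k - lo) - lchoose(m + n, k)
  for (i in seq_along(support)[-1L]) {
    x <- support[i]
    logp[i] <- logp[i - 1L] +
      log((m - x + 1) / x) + log((k - x + 1) / (n - k + x))
  }
  p <- exp(logp)
  sum(p[p <= p[support == a] * (1 + 1e-7)])
}

# ADI recomputed straight from an event list (no matrix stage).
adi_oracle <- function(events, ids) {
  vapply(ids, function(i) {
    opp_props <- vapply(setdiff(ids, i), function(j) {
      wins <- sum(events$winner == i & events$loser == j & events$decided)
      losses <- sum(events$winner == j & events$loser == i & events$decided)
      if (wins + losses == 0) NA_real_ else wins / (wins + losses)
    }, numeric(1))
    if (all(is.na(opp_props))) NA_real_ else mean(opp_props, na.rm = TRUE)
  }, numeric(1))
}

# Exhaustive minimum-SSE 2-partition of the rows of x.
kmeans_oracle_2 <- function(x) {
  n <- nrow(x)
  best <- NULL; best_sse <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {  # fix point 1 in cluster 0
    g <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)])
    if (length(unique(g)) < 2L) next
    sse <- 0
    for (cl in 0:1) {
      xs <- x[g == cl, , drop = FALSE]
      ctr <- colMeans(xs)
      sse <- sse + sum(sweep(xs, 2L, ctr)^2)
    }
    if (sse < best_sse) { best_sse <- sse; best <- g }
  }
  list(labels = best, sse = best_sse)
}

# Row principal coordinates of indicator-matrix correspondence analysis via
# an eigendecomposition (versus the package's SVD route).
mca_oracle <- function(x) {
  P <- x / sum(x)
  r <- rowSums(P); cm <- colSums(P)
  keep <- cm > 0
  S <- (P[, keep] - outer(r, cm[keep])) / sqrt(outer(r, cm[keep]))
  eg <- eigen(S %*% t(S), symmetric = TRUE)
  pos <- eg$values > 1e-12
  coords <- diag(1 / sqrt(r)) %*% eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), nrow = sum(pos))
  list(coords = coords, values = eg$values[pos])
}

# Single-step Tukey adjusted p for balanced designs with infinite df.
tukey_oracle_balanced <- function(z, m) {
  stats::ptukey(sqrt(2) * abs(z), m, Inf, lower.tail = FALSE)
}
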
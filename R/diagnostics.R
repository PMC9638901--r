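## MCMC convergence diagnostics, vectorized across genes.

## split-Rhat: each chain is halved, potential scale reduction computed
## across the 2C half-chains. `chains` is a list of (iter x G) matrices.
.split_rhat <- function(chains) {
  n2 <- floor(nrow(chains[[1]]) / 2)
  halves <- list()
  for (m in chains) {
    halves[[length(halves) + 1L]] <- m[seq_len(n2), , drop = FALSE]
    halves[[length(halves) + 1L]] <- m[n2 + seq_len(n2), , drop = FALSE]
  }
  M <- do.call(rbind, lapply(halves, colMeans))
  V <- do.call(rbind, lapply(halves, function(h) {
    apply(h, 2, var)
  }))
  W <- colMeans(V)
  B <- n2 * apply(M, 2, var)
  out <- sqrt(((n2 - 1) / n2 * W + B / n2) / W)
  out[W == 0 & B == 0] <- 1
  out[W == 0 & B > 0] <- Inf
  out
}

## effective sample size by Geyer's initial positive sequence, per chain,
## summed over chains
.ess_chains <- function(chains) {
  G <- ncol(chains[[1]])
  total <- numeric(G)
  for (m in chains) {
    n <- nrow(m)
    lag_max <- min(n - 1, 200)
    for (j in seq_len(G)) {
      x <- m[, j]
      if (var(x) == 0) { total[j] <- total[j] + n; next }
      rho <- as.vector(acf(x, lag.max = lag_max, plot = FALSE,
                           demean = TRUE)$acf)[-1]
      ssum <- 0
      k <- 1
      while (k < length(rho)) {
        pair <- rho[k] + rho[k + 1]
        if (is.na(pair) || pair <= 0) break
        ssum <- ssum + pair
        k <- k + 2
      }
      total[j] <- total[j] + n / (1 + 2 * ssum)
    }
  }
  pmin(total, length(chains) * nrow(chains[[1]]))
}
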
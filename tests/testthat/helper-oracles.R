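# Independent brute-force oracles, written as literal loop transcriptions
# of the definitions so they share no code with the package
# implementations they check.

# n-1 SD of log2 ratios of two RQ vectors.
oracle_pair_sd <- function(a, b) {
  r <- log2(a) - log2(b)
  m <- sum(r) / length(r)
  sqrt(sum((r - m)^2) / (length(r) - 1))
}

# geNorm M for every gene of a panel (gene x sample RQ matrix).
oracle_m_values <- function(values) {
  genes <- rownames(values)
  out <- numeric(length(genes))
  names(out) <- genes
  for (j in seq_along(genes)) {
    acc <- c()
    for (k in seq_along(genes)) {
      if (k == j) next
      acc <- c(acc, oracle_pair_sd(values[j, ], values[k, ]))
    }
    out[j] <- mean(acc)
  }
  out
}

# Full stepwise exclusion by the definition (ties: drop the
# lexicographically last gene among the tied).
oracle_genorm <- function(values) {
  remaining <- sort(rownames(values))
  excl <- character()
  traj <- list()
  while (length(remaining) > 2) {
    m <- oracle_m_values(values[remaining, , drop = FALSE])
    traj[[length(traj) + 1]] <- m
    tied <- names(m)[m == max(m)]
    drop_g <- sort(tied)[length(tied)]
    excl <- c(excl, drop_g)
    remaining <- setdiff(remaining, drop_g)
  }
  pair <- sort(remaining)
  list(exclusion_order = excl, final_pair = pair,
       final_m = oracle_pair_sd(values[pair[1], ], values[pair[2], ]),
       trajectory = traj)
}

# V(n, n+1) series from a ranked gene list, via explicit geometric means.
oracle_v_series <- function(values, ranked) {
  ns <- ncol(values)
  nf <- function(n) {
    sapply(seq_len(ns), function(s) {
      prod(values[ranked[1:n], s])^(1 / n)
    })
  }
  vapply(2:(length(ranked) - 1), function(n)
    oracle_pair_sd(nf(n), nf(n + 1)), numeric(1))
}

# NormFinder stability values, literal transcription with loops.
# y: gene x sample log2 RQ matrix; groups: character vector per sample.
oracle_normfinder <- function(y, groups) {
  G <- nrow(y)
  lev <- sort(unique(groups))
  stopifnot(length(lev) == 2)
  # centre per sample
  z <- y
  for (s in seq_len(ncol(y))) z[, s] <- y[, s] - mean(y[, s])
  zbar <- s2 <- matrix(0, G, 2)
  n_g <- numeric(2)
  for (k in 1:2) {
    idx <- which(groups == lev[k])
    n_g[k] <- length(idx)
    for (i in seq_len(G)) {
      zi <- z[i, idx]
      zbar[i, k] <- mean(zi)
      s2[i, k] <- sum((zi - mean(zi))^2) / (length(zi) - 1)
    }
  }
  sig2 <- matrix(0, G, 2)
  for (k in 1:2) {
    corr <- sum(s2[, k]) / (G * (G - 1))
    for (i in seq_len(G)) sig2[i, k] <- max(0, (s2[i, k] - corr) / (1 - 2 / G))
  }
  dhat <- matrix(0, G, 2)
  for (i in seq_len(G)) for (k in 1:2)
    dhat[i, k] <- zbar[i, k] - mean(zbar[i, ])
  gamma2 <- max(0, sum(dhat^2) / ((G - 1) * 1) -
                  mean(c(sig2[, 1] / n_g[1], sig2[, 2] / n_g[2])))
  rho <- numeric(G)
  for (i in seq_len(G)) {
    parts <- numeric(2)
    for (k in 1:2) {
      v <- sig2[i, k] / n_g[k]
      shrink <- if (gamma2 > 0) gamma2 / (gamma2 + v) else 0
      parts[k] <- abs(dhat[i, k] * shrink) + sqrt(v * shrink)
    }
    rho[i] <- mean(parts)
  }
  names(rho) <- rownames(y)
  list(rho = rho, gamma2 = gamma2, z = z,
       lev = lev, n_g = n_g, s2 = s2, groups = groups)
}

# Composite (pair) stability by the same chain, reusing panel-level
# correction and gamma2, evaluated with loops.
oracle_pair_rho <- function(nf, i1, i2) {
  comp <- (nf$z[i1, ] + nf$z[i2, ]) / 2
  G <- nrow(nf$z)
  zb <- sg <- numeric(2)
  for (k in 1:2) {
    idx <- which(nf$groups == nf$lev[k])
    ck <- comp[idx]
    zb[k] <- mean(ck)
    s2_k <- sum((ck - zb[k])^2) / (length(ck) - 1)
    corr <- sum(nf$s2[, k]) / (G * (G - 1))
    sg[k] <- max(0, (s2_k - corr) / (1 - 2 / G))
  }
  dh <- zb - mean(zb)
  out <- numeric(2)
  for (k in 1:2) {
    v <- sg[k] / nf$n_g[k]
    shrink <- if (nf$gamma2 > 0) nf$gamma2 / (nf$gamma2 + v) else 0
    out[k] <- abs(dh[k] * shrink) + sqrt(v * shrink)
  }
  mean(out)
}

# Exhaustive best-pair search with the oracle stability.
oracle_best_pair <- function(y, groups) {
  nf <- oracle_normfinder(y, groups)
  genes <- sort(rownames(y))
  best <- NULL
  best_rho <- Inf
  for (i in seq_along(genes)[-length(genes)]) {
    for (j in (i + 1):length(genes)) {
      r <- oracle_pair_rho(nf, genes[i], genes[j])
      if (r < best_rho - 1e-15) {
        best_rho <- r
        best <- c(genes[i], genes[j])
      }
    }
  }
  list(pair = best, rho = best_rho)
}

# Bartlett's chi-square statistic by the textbook formula.
oracle_bartlett <- function(groups_list) {
  k <- length(groups_list)
  n <- vapply(groups_list, length, integer(1))
  N <- sum(n)
  s2 <- vapply(groups_list, stats::var, numeric(1))
  sp2 <- sum((n - 1) * s2) / (N - k)
  num <- (N - k) * log(sp2) - sum((n - 1) * log(s2))
  den <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  num / den
}
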
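# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: factorial arithmetic instead of log-gamma,
# exhaustive enumeration instead of closed forms.

# HWE exact p by direct factorial enumeration of heterozygote counts
# conditional on the allele-count margins (exact for the small n used).
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- n_Aa + 2 * n_aa
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  raw <- sapply(hets, function(h) {
    aa <- (n_a - h) / 2
    AA <- n - h - aa
    2^h * factorial(n) / (factorial(AA) * factorial(h) * factorial(aa))
  })
  probs <- raw / sum(raw)
  obs <- probs[hets == n_Aa]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# Fisher two-sided p by choose() enumeration over the free cell.
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2); hi <- min(m1, n1)
  xs <- lo:hi
  probs <- choose(m1, xs) * choose(m2, n1 - xs) / choose(m1 + m2, n1)
  obs <- probs[xs == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Hypergeometric over-representation p by enumeration (tiny universes).
oracle_hyper_p <- function(k, set_size, universe_size, draw_size) {
  xs <- 0:min(set_size, draw_size)
  probs <- choose(set_size, xs) *
    choose(universe_size - set_size, draw_size - xs) /
    choose(universe_size, draw_size)
  sum(probs[xs >= k])
}

# Maximal subset of SNPs with all VIF <= cap, by exhaustive search
# (prefers larger sets; ties broken by lexicographically first subset).
oracle_vif_subset <- function(G, cap) {
  p <- ncol(G)
  vif_ok <- function(cols) {
    if (length(cols) < 2) return(TRUE)
    for (j in seq_along(cols)) {
      y <- G[, cols[j]]
      X <- cbind(1, G[, cols[-j], drop = FALSE])
      fit <- lm.fit(X, y)
      r2 <- 1 - sum(fit$residuals^2) / (var(y) * (length(y) - 1))
      v <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
      if (v > cap) return(FALSE)
    }
    TRUE
  }
  for (size in p:1) {
    combos <- utils::combn(p, size)
    for (ci in seq_len(ncol(combos))) {
      if (vif_ok(combos[, ci])) return(combos[, ci])
    }
  }
  integer(0)
}

# Per-term OLS via lm() -- independent of the package's QR code path.
oracle_lm <- function(y, X, term) {
  df <- as.data.frame(X[, -1, drop = FALSE])
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$y <- y
  fit <- lm(y ~ ., data = df)
  s <- summary(fit)$coefficients
  # term indexes columns of X (with intercept first); lm orders the same way
  list(B = s[term, 1], SE = s[term, 2], t = s[term, 3], p = s[term, 4])
}

# Small random scan design with optional missing genotypes.
random_design <- function(n = 40, n_snps = 4, n_cpgs = 3, n_cov = 2,
                          miss = 0.1, seed = 1) {
  set.seed(seed)
  G <- matrix(rbinom(n * n_snps, 1, runif(n_snps, 0.2, 0.6)),
              n, n_snps, byrow = TRUE,
              dimnames = list(NULL, paste0("s", seq_len(n_snps))))
  if (miss > 0) G[matrix(runif(n * n_snps) < miss, n, n_snps)] <- NA
  M <- matrix(runif(n * n_cpgs, 0.2, 0.8), n, n_cpgs,
              dimnames = list(NULL, paste0("c", seq_len(n_cpgs))))
  E <- rnorm(n)
  C <- as.data.frame(matrix(rnorm(n * n_cov), n, n_cov))
  names(C) <- paste0("cov", seq_len(n_cov))
  list(M = M, G = G, E = E, C = C)
}
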
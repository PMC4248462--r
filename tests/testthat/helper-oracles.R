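# Independent brute-force oracles used across the test files. These never
# call the implementation paths they check.

# random diallelic log-GL matrix (individuals x 3), moderately informative
random_gl3 <- function(n, scale = 2) {
  matrix(-abs(rnorm(3 * n, sd = scale)), n, 3)
}

# exhaustive-enumeration SAF oracle: p(X | D = j) = sum over all genotype
# configurations with sum g = j of prod_i L_i(g_i) w(g_i), / choose(2n, j)
saf_oracle <- function(gl3s) {
  n <- nrow(gl3s)
  w <- c(1, 2, 1)
  configs <- as.matrix(expand.grid(rep(list(0:2), n)))
  p <- numeric(2 * n + 1)
  for (r in seq_len(nrow(configs))) {
    g <- configs[r, ]
    term <- prod(exp(gl3s[cbind(seq_len(n), g + 1)]) * w[g + 1])
    p[sum(g) + 1] <- p[sum(g) + 1] + term
  }
  p <- p / choose(2 * n, 0:(2 * n))
  log(p) - max(log(p))
}

# exhaustive genotype-posterior oracle under an SFS prior
posterior_sfs_oracle <- function(gl3s, gamma, i) {
  n <- nrow(gl3s)
  w <- c(1, 2, 1)
  configs <- as.matrix(expand.grid(rep(list(0:2), n)))
  post <- numeric(3)
  for (r in seq_len(nrow(configs))) {
    g <- configs[r, ]
    j <- sum(g)
    term <- gamma[j + 1] * prod(exp(gl3s[cbind(seq_len(n), g + 1)]) * w[g + 1]) /
      choose(2 * n, j)
    post[g[i] + 1] <- post[g[i] + 1] + term
  }
  post / sum(post)
}

# classical unweighted delete-1 jackknife for D over equal-information blocks
delete1_jackknife_oracle <- function(nabba, nbaba) {
  B <- length(nabba)
  A <- sum(nabba); Bb <- sum(nbaba)
  theta <- (A - Bb) / (A + Bb)
  loo <- vapply(seq_len(B), function(b) {
    (A - nabba[b] - (Bb - nbaba[b])) / (A - nabba[b] + Bb - nbaba[b])
  }, numeric(1))
  jack <- B * theta - (B - 1) * mean(loo)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(D = theta, jackEst = jack, SE = se)
}

# 2x2 allele-count likelihood-ratio G-test from genotype count vectors
gtest_oracle <- function(geno_cases, geno_controls) {
  a1 <- sum(geno_cases); n1 <- 2 * length(geno_cases)
  a2 <- sum(geno_controls); n2 <- 2 * length(geno_controls)
  ll <- function(k, n, p) {
    if (p <= 0) return(ifelse(k == 0, 0, -Inf))
    if (p >= 1) return(ifelse(k == n, 0, -Inf))
    k * log(p) + (n - k) * log(1 - p)
  }
  2 * (ll(a1, n1, a1 / n1) + ll(a2, n2, a2 / n2) -
         ll(a1 + a2, n1 + n2, (a1 + a2) / (n1 + n2)))
}

# certain-genotype GL3 rows: ~0 log-likelihood for the true genotype,
# big negative elsewhere
certain_gl3 <- function(genotypes, logl_off = -1000) {
  n <- length(genotypes)
  m <- matrix(logl_off, n, 3)
  m[cbind(seq_len(n), genotypes + 1)] <- 0
  m
}
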
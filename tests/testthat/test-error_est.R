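# Base error-rate estimation

test_that("mismatch matrices tabulate outgroup vs observed bases", {
  mm <- mismatch_matrix(c("A", "A", "C"), c("A", "A", "C"))
  expect_equal(sum(diag(mm$counts)), 3)
  expect_equal(sum(mm$rates) - sum(diag(mm$rates)), 0)

  obs <- c(rep("A", 9), "G")
  mm <- mismatch_matrix(obs, rep("A", 10))
  expect_equal(mm$rates["A", "G"], 0.1)
  expect_equal(mm$rates["A", "A"], 0.9)

  # NA and non-ACGT entries are skipped
  mm <- mismatch_matrix(c("A", NA, "C"), c("A", "A", NA))
  expect_equal(sum(mm$counts), 1)
})

test_that("raw mismatch rates recover a symmetric error rate", {
  set.seed(44)
  S <- 1e5
  anc <- sample(c("A", "C", "G", "T"), S, TRUE)
  err <- runif(S) < 0.01
  obs <- anc
  # flip to one of the three other bases uniformly
  obs[err] <- vapply(anc[err], function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
  mm <- mismatch_matrix(obs, anc)
  off <- mm$rates[row(mm$rates) != col(mm$rates)]
  # ~2.5e4 sites per ancestral base: 4 sd of the binomial rate is ~1.5e-3
  expect_true(all(abs(off - 0.01 / 3) < 1.5e-3))
  expect_equal(mean(off), 0.01 / 3, tolerance = 0.15)
})

test_that("calibration returns identity when sample matches the perfect individual", {
  set.seed(52)
  anc <- sample(c("A", "C", "G", "T"), 2e4, TRUE)
  div <- runif(2e4) < 0.01
  obs <- anc
  obs[div] <- vapply(anc[div], function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
  mm <- mismatch_matrix(obs, anc)
  E <- calibrated_error(mm, mm)
  expect_equal(E, diag(4), ignore_attr = TRUE, tolerance = 1e-3)
})

test_that("calibration recovers an asymmetric excess error rate", {
  set.seed(63)
  S <- 1e6
  bs0 <- c("A", "C", "G", "T")
  P <- matrix(0.01 / 3, 4, 4, dimnames = list(bs0, bs0))
  diag(P) <- 0.99                      # 1% divergence, symmetric
  E_true <- diag(4)
  dimnames(E_true) <- list(bs0, bs0)
  E_true["C", "T"] <- 0.02
  E_true["C", "C"] <- 0.98             # damage-like C->T sample error
  bs <- c("A", "C", "G", "T")
  anc <- sample(1:4, S, TRUE)
  n_anc <- tabulate(anc, 4)
  perfect_counts <- sample_counts <- matrix(0, 4, 4, dimnames = list(bs, bs))
  M <- P %*% E_true
  for (a in 1:4) {
    perfect_counts[a, ] <- as.vector(rmultinom(1, n_anc[a], P[a, ]))
    sample_counts[a, ] <- as.vector(rmultinom(1, n_anc[a], M[a, ]))
  }
  mk <- function(cnt) structure(list(counts = cnt,
                                     rates = cnt / rowSums(cnt)),
                                class = "mismatch_matrix")
  E_hat <- calibrated_error(mk(sample_counts), mk(perfect_counts))
  expect_equal(E_hat["C", "T"], 0.02, tolerance = 0.15)
  others <- E_hat[row(E_hat) != col(E_hat) &
                    !(row(E_hat) == 2 & col(E_hat) == 4)]
  expect_true(all(others <= 0.005))
})

test_that("a zero-count ancestral row yields an identity row with a warning", {
  cnt <- matrix(0L, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  cnt["A", "A"] <- 100L; cnt["C", "C"] <- 90L; cnt["C", "T"] <- 10L
  cnt["G", "G"] <- 100L
  mk <- function(ct) structure(list(counts = ct,
                                    rates = ct / pmax(rowSums(ct), 1)),
                               class = "mismatch_matrix")
  perfect <- mk(diag(c(100L, 100L, 100L, 0L)))
  expect_warning(E <- calibrated_error(mk(cnt), perfect), "T")
  expect_equal(E[4, ], c(0, 0, 0, 1), ignore_attr = TRUE)
})

test_that("label permutation permutes the calibrated matrix consistently", {
  set.seed(70)
  cnt <- matrix(rpois(16, 50), 4, 4) + diag(4) * 5000
  dimnames(cnt) <- list(c("A","C","G","T"), c("A","C","G","T"))
  pcnt <- matrix(rpois(16, 10), 4, 4) + diag(4) * 8000
  dimnames(pcnt) <- dimnames(cnt)
  mk <- function(ct) structure(list(counts = ct, rates = ct / rowSums(ct)),
                               class = "mismatch_matrix")
  E <- calibrated_error(mk(cnt), mk(pcnt))
  perm <- c(2, 1, 4, 3)
  E_perm <- calibrated_error(mk(cnt[perm, perm]), mk(pcnt[perm, perm]))
  expect_equal(unname(E_perm), unname(E[perm, perm]), tolerance = 1e-4)
})

test_that("joint error/frequency EM has the right fixed points", {
  # error-free certain data -> identity error matrix
  set.seed(81)
  sim <- sim_onepop(10, 400, depth = 6, err = 0, seed = 82)
  obs <- sim_sample_bases(sim, seed = 83)
  keep <- rowSums(is.na(obs)) == 0
  fit <- joint_error_freq_em(obs[keep, ], max_iter = 50)
  expect_equal(unname(fit$E), diag(4), tolerance = 1e-6)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("joint EM recovers a symmetric error rate at scale", {
  # polymorphic sites only, so frequency and error separate
  sim <- sim_onepop(20, 5e4, depth = 4, err = 0.005,
                    sfs = neutral_sfs(40, invariant_mass = 0), seed = 90)
  obs <- sim_sample_bases(sim, seed = 91)
  keep <- rowSums(!is.na(obs)) >= 10
  fit <- joint_error_freq_em(obs[keep, ], max_iter = 60)
  off <- mean(fit$E[row(fit$E) != col(fit$E)]) * 3  # total error rate
  expect_gte(off, 0.003)
  expect_lte(off, 0.007)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("with the error matrix fixed to truth the EM reproduces MAF estimates", {
  set.seed(95)
  eps <- 0.01
  E <- matrix(eps / 3, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  diag(E) <- 1 - eps
  sim <- sim_onepop(15, 60, depth = 5, err = eps,
                    sfs = neutral_sfs(30, invariant_mass = 0), seed = 96)
  obs <- sim_sample_bases(sim, seed = 97)
  keep <- rowSums(is.na(obs)) == 0
  obs <- obs[keep, ]
  fit <- joint_error_freq_em(obs, fix_E = E, tol = 1e-12, max_iter = 500)
  # oracle: per-site EM on type-specific single-base GL3s with the same
  # major/minor polarization
  for (s in c(1, 5, 10)) {
    gl3s <- t(vapply(seq_len(ncol(obs)), function(i) {
      gl10 <- gl10_type_specific(list(base = obs[s, i]), E)
      unname(gl3_from_gl10(gl10, fit$major[s], fit$minor[s]))
    }, numeric(3)))
    expect_equal(fit$f[s], estimate_maf_em(gl3s, tol = 1e-12), tolerance = 1e-4)
  }
})
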
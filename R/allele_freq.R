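# Population allele frequency estimation and SNP discovery from diallelic
# genotype likelihoods. Throughout, `gl3s` is an individuals x 3 matrix of
# log-likelihoods for (major-hom, het, minor-hom); an individual with no
# reads has a flat row (all values equal) and is excluded from the count of
# individuals used.

flat_rows <- function(gl3s) {
  apply(gl3s, 1L, function(r) max(r) - min(r) < 1e-12)
}

hwe_probs <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)

#' Log-likelihood of a population allele frequency
#'
#' `sum_i log sum_g L_i(g) * HWE(g; f)` over individuals with data, with the
#' HWE genotype prior `((1-f)^2, 2f(1-f), f^2)`. Likelihood rescaling per
#' individual shifts the value by a constant, so likelihood-ratio statistics
#' are unaffected.
#'
#' @param gl3s Individuals x 3 matrix of log genotype likelihoods.
#' @param f Allele frequency in `[0, 1]` (may be a vector).
#' @return Log-likelihood (vector if `f` is a vector).
#' @export
maf_loglik <- function(gl3s, f) {
  gl3s <- rbind(gl3s)
  use <- !flat_rows(gl3s)
  gl <- gl3s[use, , drop = FALSE]
  m <- apply(gl, 1L, max)
  L <- exp(gl - m)                      # n x 3, rescaled
  vapply(f, function(ff) {
    sum(m + log(L %*% hwe_probs(ff)))
  }, numeric(1))
}

#' EM estimate of the minor allele frequency
#'
#' Maximizes [maf_loglik] by EM: with current `f`, each individual's genotype
#' posterior is proportional to `L_i(g) * HWE(g; f)` and the update is the
#' mean expected allele dosage, `f' = (1/(2N')) sum_i E[g_i | f]`, where `N'`
#' counts individuals with data. The likelihood is non-decreasing across
#' iterations; the model is unimodal so any interior start converges.
#'
#' @param gl3s Individuals x 3 matrix of log genotype likelihoods.
#' @param tol Stop when `|f' - f| < tol` (default 1e-8).
#' @param max_iter Iteration cap (default 200).
#' @param f_start Interior starting frequency (default 0.1).
#' @return Estimated frequency in `[0, 1]`.
#' @export
estimate_maf_em <- function(gl3s, tol = 1e-8, max_iter = 200L, f_start = 0.1) {
  gl3s <- rbind(gl3s)
  use <- !flat_rows(gl3s)
  if (!any(use)) stop("no individual has data (all genotype likelihoods flat)")
  gl <- gl3s[use, , drop = FALSE]
  L <- exp(gl - apply(gl, 1L, max))
  n_used <- nrow(L)
  f <- f_start
  for (it in seq_len(max_iter)) {
    W <- L * rep(hwe_probs(f), each = n_used)
    Eg <- (W[, 2] + 2 * W[, 3]) / rowSums(W)
    f_new <- sum(Eg) / (2 * n_used)
    done <- abs(f_new - f) < tol
    f <- f_new
    if (done) break
  }
  # EM approaches the boundaries only asymptotically (and can stall at an
  # interior stationary point when the mixture likelihood is multimodal);
  # return whichever of the EM point and the boundaries attains the larger
  # likelihood
  cand <- c(f, 0, 1)
  ll <- vapply(cand, function(ff) sum(log(L %*% hwe_probs(ff))), numeric(1))
  cand[which.max(ll)]
}

#' Likelihood-ratio test of a site being variable
#'
#' SNP-discovery test: compares the likelihood at the EM-estimated frequency
#' with the likelihood at `f = 0`; `LRT = 2 (ll(f_hat) - ll(0))` with a
#' chi-square(1 df) p-value. The null lies on the boundary of the parameter
#' space, so the plain chi-square reference is conservative; a
#' half-mixture `0.5 chisq(0) + 0.5 chisq(1)` reference is available via
#' `boundary_mix = TRUE`.
#'
#' @inheritParams estimate_maf_em
#' @param boundary_mix Use the boundary half-mixture null (default FALSE).
#' @return List with `f_hat`, `n_used`, `loglik_at_f_hat`, `loglik_at_0`,
#'   `lrt` and `p_value`.
#' @export
snp_lrt <- function(gl3s, tol = 1e-8, max_iter = 200L, boundary_mix = FALSE) {
  gl3s <- rbind(gl3s)
  f_hat <- estimate_maf_em(gl3s, tol = tol, max_iter = max_iter)
  ll1 <- maf_loglik(gl3s, f_hat)
  ll0 <- maf_loglik(gl3s, 0)
  lrt <- 2 * (ll1 - ll0)
  if (lrt < -1e-9) stop("negative LRT beyond numerical tolerance")
  lrt <- max(lrt, 0)
  p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  if (boundary_mix) p <- if (lrt == 0) 1 else p / 2
  list(f_hat = f_hat, n_used = sum(!flat_rows(gl3s)),
       loglik_at_f_hat = ll1, loglik_at_0 = ll0, lrt = lrt, p_value = p)
}

#' Allele frequency from genotype posterior probabilities
#'
#' For externally imputed genotype probabilities (e.g. BEAGLE input):
#' `f = mean_i (P_i(het) + 2 P_i(minor-hom)) / 2`.
#'
#' @param gps Individuals x 3 matrix of genotype probabilities
#'   (major-hom, het, minor-hom).
#' @return Frequency in `[0, 1]`.
#' @export
maf_from_gp <- function(gps) {
  gps <- rbind(gps)
  mean((gps[, 2] + 2 * gps[, 3]) / 2)
}

#' Case/control allele-frequency association test
#'
#' Likelihood-ratio test of equal allele frequencies in two groups:
#' `LRT = 2 [ll_cases(f_cases) + ll_controls(f_controls) - ll_pooled(f_pooled)]`
#' against chi-square with 1 df. With certain genotypes this is the classical
#' 2x2 allele-count G-test.
#'
#' @param gl3s_cases,gl3s_controls Individuals x 3 log genotype-likelihood
#'   matrices for the two groups.
#' @return List with the group and pooled frequency estimates, `lrt` and
#'   `p_value`.
#' @export
case_control_lrt <- function(gl3s_cases, gl3s_controls) {
  gl3s_cases <- rbind(gl3s_cases)
  gl3s_controls <- rbind(gl3s_controls)
  pooled <- rbind(gl3s_cases, gl3s_controls)
  f1 <- estimate_maf_em(gl3s_cases)
  f2 <- estimate_maf_em(gl3s_controls)
  f0 <- estimate_maf_em(pooled)
  lrt <- 2 * (maf_loglik(gl3s_cases, f1) + maf_loglik(gl3s_controls, f2) -
                maf_loglik(pooled, f0))
  lrt <- max(lrt, 0)
  list(f_cases = f1, f_controls = f2, f_pooled = f0, lrt = lrt,
       p_value = stats::pchisq(lrt, df = 1L, lower.tail = FALSE))
}
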
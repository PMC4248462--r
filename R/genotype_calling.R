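# Genotype posterior probabilities under three priors (uniform, population
# allele frequency, sample-wide SFS) and posterior-cutoff genotype calling.

#' Genotype posterior with a uniform prior
#'
#' The normalized likelihood itself (maximum-likelihood calling): the triple
#' proportional to `exp(GL3)`.
#'
#' @param gl3 Length-3 vector of log genotype likelihoods.
#' @return Probability triple summing to 1.
#' @export
posterior_uniform <- function(gl3) {
  p <- exp(gl3 - max(gl3))
  p / sum(p)
}

#' Genotype posterior with an allele-frequency (HWE) prior
#'
#' Triple proportional to `exp(GL3) * ((1-f)^2, 2f(1-f), f^2)` for an
#' estimated population frequency `f` of the second allele.
#'
#' @param gl3 Length-3 vector of log genotype likelihoods.
#' @param f Population allele frequency in `[0, 1]`.
#' @return Probability triple summing to 1.
#' @export
posterior_af <- function(gl3, f) {
  lp <- gl3 + log(c((1 - f)^2, 2 * f * (1 - f), f^2))
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Genotype posterior with the sample SFS as prior
#'
#' Posterior for individual `i` conditional on the read data of all
#' individuals and an estimated spectrum `gamma`:
#' `P(G_i = g | X, gamma) proportional to L_i(g) w(g) sum_j gamma_j
#' h^(-i)(j - g) / choose(2n, j)`, where `h^(-i)` is the SAF convolution over
#' all individuals except `i` and `w = (1, 2, 1)`. The leave-one-out
#' convolution is recomputed per individual (no division), which is
#' numerically safe at desk scale.
#'
#' @param gl3s Individuals x 3 matrix of polarized log genotype likelihoods
#'   (ancestral-hom, het, derived-hom).
#' @param gamma Spectrum over `0..2n` derived alleles (need not be
#'   normalized).
#' @param i Index of the focal individual.
#' @return Probability triple summing to 1.
#' @export
posterior_sfs <- function(gl3s, gamma, i) {
  gl3s <- rbind(gl3s)
  n <- nrow(gl3s)
  stopifnot(length(gamma) == 2L * n + 1L, i >= 1L, i <= n)
  lw <- log(c(1, 2, 1))
  logh <- saf_convolve(gl3s[-i, , drop = FALSE])  # length 2(n-1)+1, max 0
  lgamma_ <- log(gamma)
  lch <- lchoose(2 * n, 0:(2 * n))
  lp <- vapply(0:2, function(g) {
    j <- g:(g + 2L * (n - 1L))               # counts reachable given G_i = g
    lprior <- logsumexp(lgamma_[j + 1L] + logh[j - g + 1L] - lch[j + 1L])
    gl3s[i, g + 1L] + lw[g + 1L] + lprior
  }, numeric(1))
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Call genotypes from posterior triples
#'
#' The call is the posterior argmax (ties break to the lowest genotype
#' index); a call whose posterior falls below `cutoff` is set to missing.
#' `cutoff = 0` disables missingness.
#'
#' @param triples Individuals x 3 matrix of posterior probabilities (or one
#'   triple).
#' @param cutoff Posterior required to emit a call (default 0).
#' @return Data frame with integer `call` (0, 1, 2 or NA) and `score` (the
#'   posterior of the argmax genotype).
#' @export
call_genotypes <- function(triples, cutoff = 0) {
  triples <- rbind(triples)
  idx <- apply(triples, 1L, which.max)
  score <- triples[cbind(seq_len(nrow(triples)), idx)]
  call <- idx - 1L
  call[score < cutoff] <- NA_integer_
  data.frame(call = call, score = score)
}
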
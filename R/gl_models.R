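#' Phred quality to error probability
#'
#' Converts a phred base-quality score to an error probability
#' `10^(-q/10)`, capped at 0.75: with a four-letter alphabet a base whose
#' error probability reaches 3/4 carries no information, and allowing larger
#' values would make `1 - eps` negative in the likelihood models.
#'
#' @param q Numeric vector of phred scores (>= 0).
#' @return Error probabilities in (0, 0.75].
#' @export
phred_to_error <- function(q) {
  stopifnot(all(q >= 0))
  pmin(10^(-q / 10), 0.75)
}

# reads -> per-read probability matrix P[r, a] = P(observed base r | true allele a)
read_allele_probs <- function(base, eps) {
  bi <- base_index(base)
  P <- matrix(rep(eps / 3, each = 4L), nrow = length(base), ncol = 4L,
              byrow = TRUE)
  P[cbind(seq_along(bi), bi)] <- 1 - eps
  P
}

gl10_from_probs <- function(P) {
  gl <- vapply(seq_len(10L), function(g) {
    a1 <- base_index(GENO10[g, 1])
    a2 <- base_index(GENO10[g, 2])
    sum(log(0.5 * P[, a1] + 0.5 * P[, a2]))
  }, numeric(1))
  names(gl) <- GENO10_NAMES
  gl
}

#' Genotype likelihoods, independent-reads (GATK-style) model
#'
#' Log-likelihood of each of the 10 unordered diploid genotypes given a set
#' of reads: `log L(A1A2) = sum_reads log(0.5 P(b|A1) + 0.5 P(b|A2))` with
#' `P(b|A) = 1 - eps` when `b == A` and `eps/3` otherwise, `eps` from
#' [phred_to_error]. Likelihoods are defined up to a per-site constant; no
#' rescaling is applied here. An individual with no reads returns all zeros
#' (uninformative).
#'
#' @param reads List with character vector `base` and numeric vector `qual`.
#' @return Named numeric vector of 10 log-likelihoods (order AA,AC,...,TT).
#' @export
gl10_gatk <- function(reads) {
  if (length(reads$base) == 0L)
    return(stats::setNames(numeric(10L), GENO10_NAMES))
  eps <- phred_to_error(reads$qual)
  gl10_from_probs(read_allele_probs(reads$base, eps))
}

#' Genotype likelihoods under a type-specific error matrix
#'
#' As [gl10_gatk] but with `P(b|A) = E[A, b]` taken from a 4x4 row-stochastic
#' error matrix (rows: true base; columns: observed base). Base qualities are
#' not used; the matrix carries the error model. When `E` is symmetric with
#' all off-diagonals `eps/3` this reproduces [gl10_gatk] at fixed `eps`.
#'
#' @param reads List with character vector `base` (and optionally `qual`,
#'   ignored).
#' @param E 4x4 error matrix `E[a, b] = P(read b | true a)`, rows/cols in
#'   A,C,G,T order.
#' @return Named numeric vector of 10 log-likelihoods.
#' @export
gl10_type_specific <- function(reads, E) {
  stopifnot(is.matrix(E), all(dim(E) == c(4L, 4L)))
  if (length(reads$base) == 0L)
    return(stats::setNames(numeric(10L), GENO10_NAMES))
  P <- t(E)[base_index(reads$base), , drop = FALSE]  # P[r, a] = E[a, b_r]
  gl10_from_probs(P)
}

#' Infer the major and minor allele from genotype likelihoods
#'
#' Brute-force over the six allele pairs (a1, a2): picks the pair maximizing
#' `sum_i log(1/4 L_i(a1a1) + 1/2 L_i(a1a2) + 1/4 L_i(a2a2))` (a uniform
#' genotype prior within the pair). The major allele is the one with the
#' larger expected allele count under the winning pair; ties break
#' alphabetically.
#'
#' @param gl10s Matrix (individuals x 10) of log-likelihoods, columns in
#'   AA,AC,...,TT order, or a list of [gl10_gatk] vectors.
#' @return List with `major`, `minor` and the pair log-score `score`.
#' @export
infer_major_minor <- function(gl10s) {
  if (is.list(gl10s)) gl10s <- do.call(rbind, gl10s)
  stopifnot(ncol(gl10s) == 10L, nrow(gl10s) >= 1L)
  pairs <- which(GENO10[, 1] != GENO10[, 2])  # the 6 heterozygous pairs
  best <- NULL
  for (g in pairs) {
    a1 <- GENO10[g, 1]
    a2 <- GENO10[g, 2]
    hom1 <- match(paste0(a1, a1), GENO10_NAMES)
    hom2 <- match(paste0(a2, a2), GENO10_NAMES)
    contrib <- cbind(gl10s[, hom1] + log(0.25), gl10s[, g] + log(0.5),
                     gl10s[, hom2] + log(0.25))
    score <- sum(row_logsumexp(contrib))
    if (is.null(best) || score > best$score + 1e-12) {
      # expected count of a1 per individual under the within-pair posterior
      post <- exp(contrib - row_logsumexp(contrib))
      cnt1 <- sum(2 * post[, 1] + post[, 2])
      cnt2 <- sum(2 * post[, 3] + post[, 2])
      mm <- if (cnt1 > cnt2 + 1e-12) c(a1, a2)
            else if (cnt2 > cnt1 + 1e-12) c(a2, a1)
            else sort(c(a1, a2))       # tie: alphabetical
      best <- list(major = mm[1], minor = mm[2], score = score)
    }
  }
  best
}

#' Project 10-genotype likelihoods onto a diallelic basis
#'
#' Selects the (major/major, major/minor, minor/minor) entries of a GL10
#' vector, giving the 3-genotype likelihood basis used by the allele
#' frequency, SAF and genotype-calling machinery.
#'
#' @param gl10 Named numeric vector of 10 log-likelihoods.
#' @param major,minor Allele symbols.
#' @return Numeric length-3 vector with attributes `major` and `minor`.
#' @export
gl3_from_gl10 <- function(gl10, major, minor) {
  het <- paste0(sort(c(major, minor)), collapse = "")
  out <- unname(gl10[c(paste0(major, major), het, paste0(minor, minor))])
  attr(out, "major") <- major
  attr(out, "minor") <- minor
  out
}

#' Vectorized diallelic genotype likelihoods from base counts
#'
#' Fast path for constant-quality data (e.g. simulator output): computes the
#' same per-read independent-reads model as [gl10_gatk] projected onto the
#' (ref-allele hom, het, alt-allele hom) basis, but vectorized over all
#' sites and individuals from per-base read counts. Reads carrying neither
#' allele contribute `eps/3` under every genotype, a per-site constant that
#' is retained so results match [gl10_gatk] exactly.
#'
#' @param counts Integer array sites x individuals x 4 (base order A,C,G,T).
#' @param a1,a2 Per-site allele symbols (first and second allele; genotype g
#'   counts copies of `a2`).
#' @param eps Scalar error probability for every read.
#' @return Array sites x individuals x 3 of log-likelihoods.
#' @export
gl3_from_counts <- function(counts, a1, a2, eps) {
  S <- dim(counts)[1]
  I <- dim(counts)[2]
  stopifnot(dim(counts)[3] == 4L, length(a1) == S, length(a2) == S)
  i1 <- base_index(a1)
  i2 <- base_index(a2)
  out <- array(0, dim = c(S, I, 3L))
  for (g in 0:2) {
    pa <- 1 - g / 2     # weight on allele a1
    for (b in 1:4) {
      p_b_a1 <- ifelse(i1 == b, 1 - eps, eps / 3)
      p_b_a2 <- ifelse(i2 == b, 1 - eps, eps / 3)
      lg <- log(pa * p_b_a1 + (1 - pa) * p_b_a2)   # per-site vector
      out[, , g + 1L] <- out[, , g + 1L] + counts[, , b] * lg
    }
  }
  out
}
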
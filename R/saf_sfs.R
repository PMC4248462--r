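# Sample-allele-frequency (SAF) likelihoods and site-frequency-spectrum (SFS)
# estimation. The SAF vector at a site is p(all read data | j derived alleles
# in the sample), j = 0..2n, computed by a dynamic programme over individuals;
# 1D and joint 2D spectra are estimated from SAF vectors by EM.

# elementwise log(exp(a) + exp(b) + exp(c)), -Inf safe; works on vectors
# and matrices of equal shape
lse3 <- function(a, b, c) {
  m <- pmax(a, b, c)
  out <- m + log(exp(a - m) + exp(b - m) + exp(c - m))
  out[m == -Inf] <- -Inf
  out
}

# Core DP used by saf_site and the SFS-prior genotype posteriors: the raw
# convolution h(j) = sum over genotype configurations with sum g = j of
# prod_k L_k(g_k) * w(g_k), w = (1, 2, 1), carried entirely in log space so
# the result cannot under- or overflow however many individuals are stacked.
# Returns the log-convolution vector of length 2n + 1, normalized to max 0.
saf_convolve <- function(gl3s) {
  lh <- 0
  lw <- log(c(1, 2, 1))
  for (k in seq_len(nrow(gl3s))) {
    l <- gl3s[k, ] + lw
    lh <- lse3(c(lh + l[1], -Inf, -Inf),
               c(-Inf, lh + l[2], -Inf),
               c(-Inf, -Inf, lh + l[3]))
    lh <- lh - max(lh)
  }
  lh
}

#' Per-site sample-allele-frequency likelihoods
#'
#' Computes `p(X | D = j)` for `j = 0..2n` from polarized diallelic genotype
#' likelihoods (ordered ancestral-hom, het, derived-hom, so the genotype
#' index counts derived alleles). The dynamic programme convolves individuals
#' with within-genotype weights `(1, 2, 1)` and divides the result for `j`
#' by `choose(2n, j)`; rescaling at each step keeps the computation immune
#' to underflow for hundreds of individuals. The result is log-normalized so
#' its maximum is 0 (SFS likelihoods are invariant to per-site constants).
#'
#' @param gl3s Individuals x 3 matrix of log genotype likelihoods, polarized
#'   by the ancestral allele.
#' @return Numeric vector of length `2n + 1` of normalized log-likelihoods.
#' @export
saf_site <- function(gl3s) {
  gl3s <- rbind(gl3s)
  n <- nrow(gl3s)
  if (n == 0L) stop("saf_site requires at least one individual")
  logp <- saf_convolve(gl3s) - lchoose(2 * n, 0:(2 * n))
  logp - max(logp)
}

#' Vectorized SAF likelihoods for many sites
#'
#' Runs the [saf_site] dynamic programme for all sites at once (the per-step
#' state is a sites x (2n+1) matrix), producing a [saf_table]. Identical to
#' calling [saf_site] per site.
#'
#' @param gl3_array Array sites x individuals x 3 of polarized log genotype
#'   likelihoods.
#' @param chrom,pos Site coordinates (defaults: `"chr1"`, `1:S`).
#' @return A [saf_table].
#' @export
saf_all_sites <- function(gl3_array, chrom = NULL, pos = NULL) {
  S <- dim(gl3_array)[1]
  n <- dim(gl3_array)[2]
  stopifnot(dim(gl3_array)[3] == 3L, n >= 1L)
  if (is.null(pos)) pos <- seq_len(S)
  if (is.null(chrom)) chrom <- rep("chr1", S)
  K <- 2L * n + 1L
  LH <- matrix(-Inf, S, K)
  LH[, 1] <- 0
  lw2 <- log(2)
  for (k in seq_len(n)) {
    gl <- gl3_array[, k, , drop = FALSE]
    dim(gl) <- c(S, 3L)
    ncol_k <- 2L * k + 1L
    A <- LH + gl[, 1]                  # per-site vectors recycle down rows
    B <- C <- matrix(-Inf, S, K)
    B[, 2:ncol_k] <- LH[, 1:(ncol_k - 1L)] + (gl[, 2] + lw2)
    C[, 3:ncol_k] <- LH[, 1:(ncol_k - 2L)] + gl[, 3]
    LH <- lse3(A, B, C)
    rmx <- LH[, 1]
    for (j in 2:ncol_k) rmx <- pmax(rmx, LH[, j])
    LH <- LH - rmx
  }
  logp <- LH - rep(lchoose(2 * n, 0:(2 * n)), each = S)
  logp <- logp - apply(logp, 1L, max)
  saf_table(chrom, pos, logp, n)
}

#' Log-likelihood of a 1D site frequency spectrum
#'
#' `sum_s log sum_j gamma_j p(X_s | D = j)` up to per-site constants.
#'
#' @param saf A [saf_table] (or a sites x (2n+1) matrix of normalized
#'   log SAF values).
#' @param gamma Probability vector of length `2n + 1`.
#' @return Log-likelihood.
#' @export
loglik_sfs_1d <- function(saf, gamma) {
  P <- exp(if (inherits(saf, "saf_table")) saf$logp else as.matrix(saf))
  stopifnot(ncol(P) == length(gamma))
  sum(log(P %*% gamma))
}

#' EM estimation of the 1D site frequency spectrum
#'
#' Standard mixture-weight EM for the spectrum `gamma` over derived-allele
#' counts: `gamma_j' = (1/N) sum_s gamma_j p(X_s|D=j) / sum_k gamma_k
#' p(X_s|D=k)`. Starts from the uniform spectrum; the log-likelihood is
#' non-decreasing at every iteration and the run stops when the relative
#' gain drops below `tol`.
#'
#' @inheritParams loglik_sfs_1d
#' @param tol Relative log-likelihood gain at which to stop (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @return List with `gamma` (the estimated spectrum), `loglik`, `n_iter`,
#'   `converged` and the per-iteration `loglik_trace`.
#' @export
sfs_em_1d <- function(saf, tol = 1e-8, max_iter = 500L) {
  P <- exp(if (inherits(saf, "saf_table")) saf$logp else as.matrix(saf))
  S <- nrow(P)
  if (S == 0L) stop("no sites")
  K <- ncol(P)
  gamma <- rep(1 / K, K)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- P * rep(gamma, each = S)
    denom <- rowSums(W)
    ll <- sum(log(denom))
    trace <- c(trace, ll)
    gamma <- colSums(W / denom) / S
    if (it > 1L && (ll - ll_old) < tol * (abs(ll_old) + 1e-300)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(gamma = gamma, loglik = trace[length(trace)], n_iter = length(trace),
       converged = converged, loglik_trace = trace)
}

# Intersect two SAF tables on exact (chrom, pos) keys; order follows saf1.
align_safs <- function(saf1, saf2) {
  k1 <- paste(saf1$chrom, saf1$pos, sep = "\r")
  k2 <- paste(saf2$chrom, saf2$pos, sep = "\r")
  idx1 <- which(k1 %in% k2)
  idx2 <- match(k1[idx1], k2)
  list(
    saf1 = saf_table(saf1$chrom[idx1], saf1$pos[idx1],
                     saf1$logp[idx1, , drop = FALSE], saf1$n_individuals),
    saf2 = saf_table(saf2$chrom[idx2], saf2$pos[idx2],
                     saf2$logp[idx2, , drop = FALSE], saf2$n_individuals))
}

#' Log-likelihood of a joint 2D site frequency spectrum
#'
#' For two populations with aligned sites, the per-site likelihood is
#' `sum_ij gamma_ij p(X1_s | D1 = i) p(X2_s | D2 = j)`; this returns the sum
#' of its logs over sites (up to per-site constants). Sites must already be
#' aligned (same order, same coordinates); use [sfs_em_2d] for automatic
#' intersection.
#'
#' @param saf1,saf2 [saf_table] objects (or matrices) with equal site counts.
#' @param gamma Matrix `(2n1+1) x (2n2+1)` of probabilities.
#' @return Log-likelihood.
#' @export
loglik_sfs_2d <- function(saf1, saf2, gamma) {
  P1 <- exp(if (inherits(saf1, "saf_table")) saf1$logp else as.matrix(saf1))
  P2 <- exp(if (inherits(saf2, "saf_table")) saf2$logp else as.matrix(saf2))
  stopifnot(nrow(P1) == nrow(P2), dim(gamma) == c(ncol(P1), ncol(P2)))
  sum(log(rowSums((P1 %*% gamma) * P2)))
}

#' EM estimation of the joint 2D site frequency spectrum
#'
#' Estimates the matrix `gamma[i, j]` of probabilities of observing `i` and
#' `j` derived alleles in populations 1 and 2 at a random site. Sites are
#' intersected on exact (chrom, pos) match; the mixture-weight EM update is
#' `gamma_ij' = (1/N) sum_s gamma_ij p(X1_s|D1=i) p(X2_s|D2=j) / L(X_s |
#' gamma)`, started from the uniform matrix, with non-decreasing
#' log-likelihood and the same stopping rule as [sfs_em_1d].
#'
#' @param saf1,saf2 [saf_table] objects for the two populations.
#' @param tol Relative log-likelihood gain at which to stop (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @return List with `gamma` (matrix), `loglik`, `n_iter`, `converged`,
#'   `loglik_trace` and `n_sites` (aligned site count).
#' @export
sfs_em_2d <- function(saf1, saf2, tol = 1e-8, max_iter = 500L) {
  al <- align_safs(saf1, saf2)
  S <- nrow(al$saf1$logp)
  if (S == 0L)
    stop("no sites shared between the two SAF tables; ",
         "2D-SFS estimation requires sites present in both populations")
  P1 <- exp(al$saf1$logp)
  P2 <- exp(al$saf2$logp)
  K1 <- ncol(P1)
  K2 <- ncol(P2)
  gamma <- matrix(1 / (K1 * K2), K1, K2)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M <- P1 %*% gamma                   # S x K2: sum_i gamma_ij P1_si
    denom <- rowSums(M * P2)            # per-site likelihood
    ll <- sum(log(denom))
    trace <- c(trace, ll)
    gamma <- gamma * crossprod(P1, P2 / denom) / S
    if (it > 1L && (ll - ll_old) < tol * (abs(ll_old) + 1e-300)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(gamma = gamma, loglik = trace[length(trace)], n_iter = length(trace),
       converged = converged, loglik_trace = trace, n_sites = S)
}

#' Write / read an estimated SFS
#'
#' 1D spectra are written as a whitespace-separated flat vector; 2D spectra
#' row-major with a one-line header `#dims K1 K2`.
#'
#' @param gamma Probability vector (1D) or matrix (2D).
#' @param path Output file path.
#' @export
write_sfs <- function(gamma, path) {
  if (is.matrix(gamma)) {
    writeLines(c(sprintf("#dims %d %d", nrow(gamma), ncol(gamma)),
                 paste(sprintf("%.15g", as.vector(t(gamma))), collapse = " ")),
               path)
  } else {
    writeLines(paste(sprintf("%.15g", gamma), collapse = " "), path)
  }
}

#' @rdname write_sfs
#' @return `read_sfs` returns the vector or matrix.
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (startsWith(lines[1], "#dims")) {
    d <- as.integer(strsplit(lines[1], "\\s+")[[1]][2:3])
    v <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
    matrix(v, d[1], d[2], byrow = TRUE)
  } else {
    as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  }
}
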
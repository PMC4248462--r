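# Type-specific base error-rate estimation: raw mismatch rates against an
# outgroup, calibration against a high-quality individual, and joint EM
# estimation of error rates and per-site allele frequencies. All estimators
# consume one sampled base per site per individual (see sample_base), which
# removes depth bias.

#' Mismatch count/rate matrix against outgroup bases
#'
#' Tabulates (outgroup/ancestral base, observed sampled base) pairs over
#' sites where both are known. The rate matrix is the row-normalized count
#' matrix; the raw mismatch rate conflates true divergence with sequencing
#' error, which [calibrated_error] corrects.
#'
#' @param obs Observed sampled bases (character vector, NA allowed).
#' @param anc Outgroup/ancestral bases (character vector, NA allowed).
#' @return List of class `mismatch_matrix` with 4x4 `counts` and `rates`
#'   (rows: ancestral base; columns: observed base; A,C,G,T order).
#' @export
mismatch_matrix <- function(obs, anc) {
  ok <- !is.na(obs) & !is.na(anc) & obs %in% BASES & anc %in% BASES
  counts <- matrix(0L, 4L, 4L, dimnames = list(BASES, BASES))
  if (any(ok)) {
    tab <- table(factor(anc[ok], BASES), factor(obs[ok], BASES))
    counts[] <- as.integer(tab)
  }
  rs <- rowSums(counts)
  rates <- counts / ifelse(rs > 0, rs, 1)
  structure(list(counts = counts, rates = rates), class = "mismatch_matrix")
}

# row-stochastic matrix from 3 free logits per row (diagonal is the
# reference category), rows in `free`; other rows identity.
logits_to_error <- function(x, free) {
  E <- diag(4)
  dimnames(E) <- list(BASES, BASES)
  k <- 0L
  for (a in which(free)) {
    z <- exp(x[k + 1:3])
    k <- k + 3L
    row <- numeric(4)
    row[-a] <- z / (1 + sum(z))
    row[a] <- 1 / (1 + sum(z))
    E[a, ] <- row
  }
  E
}

#' Error matrix calibrated against a high-quality individual
#'
#' Treats the outgroup-mismatch rates of a high-quality ("perfect")
#' individual as true divergence `P` and models the sample's observed
#' mismatch rates as the composition `P %*% E` (divergence first, then
#' sequencing error; first-order, no back-mutation — adequate at small
#' rates). `E` is estimated by maximizing the multinomial likelihood of the
#' sample's mismatch counts over row-stochastic matrices, via BFGS on
#' per-row logits (relative tolerance 1e-12). Rows of the sample count
#' matrix with no observations are not identifiable and are returned as
#' identity rows with a warning.
#'
#' @param sample_mm [mismatch_matrix] of the individual to calibrate.
#' @param perfect_mm [mismatch_matrix] of the high-quality individual over
#'   the same outgroup.
#' @return 4x4 error matrix `E[a, b] = P(read b | true a)`.
#' @export
calibrated_error <- function(sample_mm, perfect_mm) {
  C <- sample_mm$counts
  P <- perfect_mm$rates
  # rows of P with no perfect-individual data: assume no divergence
  noP <- rowSums(perfect_mm$counts) == 0
  P[noP, ] <- diag(4)[noP, ]
  free <- rowSums(C) > 0
  if (!all(free))
    warning("no observations for ancestral base(s) ",
            paste(BASES[!free], collapse = ","),
            "; returning identity row(s)")
  if (!any(free)) return(logits_to_error(numeric(0), free))
  negll <- function(x) {
    M <- P %*% logits_to_error(x, free)
    -sum(C[C > 0] * log(M[C > 0]))
  }
  x0 <- rep(log(1e-3), 3L * sum(free))
  fit <- stats::optim(x0, negll, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  logits_to_error(fit$par, free)
}

#' Joint EM estimation of error rates and per-site allele frequencies
#'
#' Estimates a type-specific error matrix and per-site population allele
#' frequencies simultaneously from one sampled base per site per individual
#' at (putatively) polymorphic sites. Each site is treated as diallelic with
#' major/minor alleles fixed from the raw base counts; the complete-data
#' model is (genotype from HWE at f_s, transmitted allele from the genotype,
#' observed base through E). The E-step computes posteriors over genotype
#' and transmitted allele; the M-step updates every `f_s` (expected allele
#' dosage) and `E` (row-normalized expected transmitted-to-observed counts),
#' so the observed-data log-likelihood is non-decreasing.
#'
#' @param obs Sites x individuals character matrix of sampled bases
#'   (NA = missing).
#' @param tol Relative log-likelihood gain at which to stop (default 1e-8).
#' @param max_iter Iteration cap (default 200).
#' @param fix_E Optional fixed 4x4 error matrix; if supplied only the
#'   frequencies are updated (useful for validation).
#' @param eps_init Initial symmetric error rate (default 0.01).
#' @return List with `E`, `f` (per-site frequencies), `major`, `minor`,
#'   `loglik_trace`, `n_iter`, `converged`.
#' @export
joint_error_freq_em <- function(obs, tol = 1e-8, max_iter = 200L,
                                fix_E = NULL, eps_init = 0.01) {
  obs <- as.matrix(obs)
  S <- nrow(obs)
  I <- ncol(obs)
  bM <- matrix(match(obs, BASES), S, I)
  # major/minor from raw counts (ties break to earlier base), fixed hereafter
  cnt <- t(apply(bM, 1L, function(r) tabulate(r[!is.na(r)], 4L)))
  maj <- max.col(cnt, ties.method = "first")
  cnt2 <- cnt
  cnt2[cbind(seq_len(S), maj)] <- -1L
  minr <- max.col(cnt2, ties.method = "first")
  majM <- matrix(maj, S, I)
  minM <- matrix(minr, S, I)
  miss <- is.na(bM)
  n_used <- rowSums(!miss)
  if (any(n_used == 0L)) stop("site with no observed bases")
  if (is.null(fix_E)) {
    E <- matrix(eps_init / 3, 4, 4, dimnames = list(BASES, BASES))
    diag(E) <- 1 - eps_init
  } else {
    E <- fix_E
  }
  f <- rep(0.1, S)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  bv <- as.vector(bM)
  idx_maj <- cbind(as.vector(majM), bv)
  idx_min <- cbind(as.vector(minM), bv)
  for (it in seq_len(max_iter)) {
    L0 <- matrix(E[idx_maj], S, I)
    L2 <- matrix(E[idx_min], S, I)
    L1 <- (L0 + L2) / 2
    W0 <- L0 * (1 - f)^2
    W1 <- L1 * 2 * f * (1 - f)
    W2 <- L2 * f^2
    den <- W0 + W1 + W2
    ll <- sum(log(den[!miss]))
    trace <- c(trace, ll)
    P0 <- W0 / den
    P1 <- W1 / den
    P2 <- W2 / den
    P0[miss] <- 0; P1[miss] <- 0; P2[miss] <- 0
    f <- rowSums(P1 + 2 * P2) / (2 * n_used)
    if (is.null(fix_E)) {
      r_maj <- L0 / (L0 + L2)          # P(transmitted = major | g = 1, b)
      w_maj <- P0 + P1 * r_maj
      w_min <- P2 + P1 * (1 - r_maj)
      w_maj[miss] <- 0; w_min[miss] <- 0
      idx16 <- (idx_maj[, 1] - 1L) * 4L + idx_maj[, 2]
      cexp <- numeric(16)
      ok <- !is.na(idx16)
      add <- rowsum(as.vector(w_maj)[ok], idx16[ok])
      cexp[as.integer(rownames(add))] <- add
      idx16m <- (idx_min[, 1] - 1L) * 4L + idx_min[, 2]
      addm <- rowsum(as.vector(w_min)[ok], idx16m[ok])
      cexp[as.integer(rownames(addm))] <- cexp[as.integer(rownames(addm))] + addm
      Cexp <- matrix(cexp, 4, 4, byrow = TRUE, dimnames = list(BASES, BASES))
      rs <- rowSums(Cexp)
      E <- Cexp / ifelse(rs > 0, rs, 1)
      E[rs == 0, ] <- diag(4)[rs == 0, ]
    }
    if (it > 1L && (ll - ll_old) < tol * (abs(ll_old) + 1e-300)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(E = E, f = f, major = BASES[maj], minor = BASES[minr],
       loglik_trace = trace, n_iter = length(trace), converged = converged)
}
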
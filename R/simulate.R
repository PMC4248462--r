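# Seedable simulator of diploid low-coverage sequencing data: genotypes drawn
# from a configured site frequency spectrum, Poisson read depth, symmetric
# base error (each wrong base with probability eps/3 — deliberately matching
# the likelihood models, so recovery tests isolate estimator error).

#' Neutral sample site frequency spectrum
#'
#' Spectrum over `0..n_chr` derived alleles: an invariant-site mass at 0 and
#' the neutral `1/j` shape over the segregating classes `1..n_chr - 1` (the
#' fixed-derived class gets no mass).
#'
#' @param n_chr Number of sampled chromosomes (2n for n diploids).
#' @param invariant_mass Probability of the zero-derived class (default 0.2;
#'   polymorphism-enriched relative to genome-wide data so spectrum recovery
#'   is informative at desk scale).
#' @return Probability vector of length `n_chr + 1`.
#' @export
neutral_sfs <- function(n_chr, invariant_mass = 0.2) {
  stopifnot(n_chr >= 2, invariant_mass >= 0, invariant_mass < 1)
  seg <- 1 / seq_len(n_chr - 1L)
  c(invariant_mass, (1 - invariant_mass) * seg / sum(seg), 0)
}

#' Correlated joint SFS from a shared ancestral frequency
#'
#' Joint spectrum for two samples drawn from populations that share their
#' allele frequencies (the limit of a very recent split): an ancestral
#' derived-allele frequency `x` follows the neutral `1/x` density on a grid,
#' and each sample's derived count is binomial at `x`, so
#' `gamma_ij = sum_x w(x) Binom(i; 2n1, x) Binom(j; 2n2, x)` plus an
#' invariant-site mass at (0, 0). Mass concentrates on the diagonal, the
#' signature of shared drift.
#'
#' @param n1_chr,n2_chr Chromosomes sampled per population (2n).
#' @param invariant_mass Extra probability at x = 0 (default 0.2, matching
#'   [neutral_sfs]).
#' @param grid Number of frequency grid points (default 100).
#' @return Matrix `(n1_chr+1) x (n2_chr+1)` summing to 1.
#' @export
shared_drift_sfs2d <- function(n1_chr, n2_chr, invariant_mass = 0.2,
                               grid = 100L) {
  x <- seq_len(grid - 1L) / grid
  w <- (1 - invariant_mass) * (1 / x) / sum(1 / x)
  g <- matrix(0, n1_chr + 1L, n2_chr + 1L)
  for (k in seq_along(x))
    g <- g + w[k] * outer(stats::dbinom(0:n1_chr, n1_chr, x[k]),
                          stats::dbinom(0:n2_chr, n2_chr, x[k]))
  g[1, 1] <- g[1, 1] + invariant_mass
  g
}

# multivariate-hypergeometric assignment of j derived alleles to n diploid
# individuals, vectorized over sites: returns S x n genotype matrix.
assign_genotypes <- function(j, n_ind) {
  S <- length(j)
  g <- matrix(0L, S, n_ind)
  rem_der <- j
  rem_tot <- rep(2L * n_ind, S)
  for (i in seq_len(n_ind)) {
    gi <- stats::rhyper(S, rem_der, rem_tot - rem_der, 2L)
    g[, i] <- gi
    rem_der <- rem_der - gi
    rem_tot <- rem_tot - 2L
  }
  g
}

# distribute `n_flip` erroneous reads uniformly over the 3 non-true bases;
# returns a length(n_flip) x 3 count matrix.
split_flips <- function(n_flip) {
  x1 <- stats::rbinom(length(n_flip), n_flip, 1 / 3)
  x2 <- stats::rbinom(length(n_flip), n_flip - x1, 1 / 2)
  cbind(x1, x2, n_flip - x1 - x2)
}

# the three base indices other than `a`, as an S x 3 matrix
other_bases <- function(a_idx) {
  o <- matrix(0L, length(a_idx), 3L)
  for (a in 1:4) {
    rows <- a_idx == a
    if (any(rows)) o[rows, ] <- matrix((1:4)[-a], sum(rows), 3L, byrow = TRUE)
  }
  o
}

# read-count array (S x I x 4) for genotypes g (S x I), given per-site
# ancestral/derived base indices and the error model
simulate_counts <- function(g, anc_idx, der_idx, depth, err) {
  S <- nrow(g)
  I <- ncol(g)
  d <- matrix(stats::rpois(S * I, depth), S, I)
  n_der <- matrix(stats::rbinom(S * I, as.vector(d), as.vector(g) / 2), S, I)
  n_anc <- d - n_der
  flat_anc <- rep(anc_idx, times = I)
  flat_der <- rep(der_idx, times = I)
  M <- matrix(0L, S * I, 4L)
  cell <- seq_len(S * I)
  fa <- stats::rbinom(S * I, as.vector(n_anc), err)
  fd <- stats::rbinom(S * I, as.vector(n_der), err)
  M[cbind(cell, flat_anc)] <- as.vector(n_anc) - fa
  M[cbind(cell, flat_der)] <- M[cbind(cell, flat_der)] + as.vector(n_der) - fd
  oa <- other_bases(flat_anc)
  od <- other_bases(flat_der)
  sa <- split_flips(fa)
  sd <- split_flips(fd)
  for (k in 1:3) {
    M[cbind(cell, oa[, k])] <- M[cbind(cell, oa[, k])] + sa[, k]
    M[cbind(cell, od[, k])] <- M[cbind(cell, od[, k])] + sd[, k]
  }
  array(M, dim = c(S, I, 4L))
}

#' Simulate one population of diploid pileup data
#'
#' Per site: a derived-allele count is drawn from `sfs` (or, with
#' `hwe = TRUE`, genotypes are drawn binomially at frequency `j/2n`),
#' genotypes are assigned by hypergeometric sampling so the realized sample
#' count equals the drawn count, read depths are Poisson(`depth`), and each
#' read shows the true allele flipped to one of the three other bases with
#' total probability `err`. All emitted bases carry the constant phred
#' score `round(-10 log10(err))`.
#'
#' @param n_ind Number of diploid individuals.
#' @param n_sites Number of sites.
#' @param depth Mean sequencing depth per individual (default 2, i.e. 2X).
#' @param err Base error rate (default 0.002, i.e. 0.2%).
#' @param sfs Spectrum over `0..2n` derived alleles (default [neutral_sfs]).
#' @param hwe Draw genotypes from HWE at `j/2n` instead of conditioning on
#'   the count (default FALSE).
#' @param seed Optional RNG seed (caller's RNG state is restored).
#' @return List of class `sim_onepop`: `chrom`, `pos`, `anc`, `der`
#'   (base symbols), `counts` (sites x individuals x 4 array, A,C,G,T
#'   order), `phred`, and truth `genotypes`, `derived_counts`, `freq`,
#'   plus the configuration.
#' @export
sim_onepop <- function(n_ind, n_sites, depth = 2, err = 0.002,
                       sfs = neutral_sfs(2 * n_ind), hwe = FALSE,
                       seed = NULL) {
  stopifnot(depth > 0, err >= 0, err < 0.75,
            length(sfs) == 2L * n_ind + 1L, all(sfs >= 0))
  with_seed(seed, {
    sfs <- sfs / sum(sfs)
    j <- sample.int(2L * n_ind + 1L, n_sites, replace = TRUE, prob = sfs) - 1L
    g <- if (hwe) {
      matrix(stats::rbinom(n_sites * n_ind, 2L, rep(j / (2 * n_ind), n_ind)),
             n_sites, n_ind)
    } else {
      assign_genotypes(j, n_ind)
    }
    anc_idx <- sample.int(4L, n_sites, replace = TRUE)
    der_idx <- ((anc_idx - 1L + sample.int(3L, n_sites, replace = TRUE)) %% 4L) + 1L
    counts <- simulate_counts(g, anc_idx, der_idx, depth, err)
    phred <- if (err > 0) max(1L, as.integer(round(-10 * log10(err)))) else 93L
    structure(list(
      chrom = rep("chr1", n_sites), pos = seq_len(n_sites),
      anc = BASES[anc_idx], der = BASES[der_idx],
      counts = counts, phred = phred,
      genotypes = g, derived_counts = as.integer(rowSums(g)), freq = j / (2 * n_ind),
      n_ind = n_ind, n_sites = n_sites, depth = depth, err = err, sfs = sfs),
      class = "sim_onepop")
  })
}

#' Simulate two populations sharing sites under a joint SFS
#'
#' Per site a pair of derived counts `(i, j)` is drawn from the joint
#' spectrum `gamma`; genotypes are assigned by count-conditioning within
#' each population and reads simulated as in [sim_onepop]. Both populations
#' share the same site list and ancestral/derived bases.
#'
#' @param n1,n2 Diploid individuals in populations 1 and 2.
#' @param n_sites Number of sites.
#' @param gamma Joint spectrum matrix `(2n1+1) x (2n2+1)`.
#' @inheritParams sim_onepop
#' @return List with `pop1` and `pop2` (each a `sim_onepop`) and the drawn
#'   `pair_counts` (sites x 2 matrix of derived counts).
#' @export
sim_twopop <- function(n1, n2, n_sites, gamma, depth = 2, err = 0.002,
                       seed = NULL) {
  stopifnot(nrow(gamma) == 2L * n1 + 1L, ncol(gamma) == 2L * n2 + 1L,
            all(gamma >= 0))
  with_seed(seed, {
    gamma <- gamma / sum(gamma)
    cell <- sample.int(length(gamma), n_sites, replace = TRUE,
                       prob = as.vector(gamma))
    i <- (cell - 1L) %% nrow(gamma)          # pop1 derived count
    j <- (cell - 1L) %/% nrow(gamma)         # pop2 derived count
    anc_idx <- sample.int(4L, n_sites, replace = TRUE)
    der_idx <- ((anc_idx - 1L + sample.int(3L, n_sites, replace = TRUE)) %% 4L) + 1L
    phred <- if (err > 0) max(1L, as.integer(round(-10 * log10(err)))) else 93L
    mk <- function(n_ind, cnt) {
      g <- assign_genotypes(cnt, n_ind)
      structure(list(
        chrom = rep("chr1", n_sites), pos = seq_len(n_sites),
        anc = BASES[anc_idx], der = BASES[der_idx],
        counts = simulate_counts(g, anc_idx, der_idx, depth, err),
        phred = phred, genotypes = g, derived_counts = as.integer(rowSums(g)),
        freq = cnt / (2 * n_ind), n_ind = n_ind, n_sites = n_sites,
        depth = depth, err = err, sfs = NULL), class = "sim_onepop")
    }
    list(pop1 = mk(n1, i), pop2 = mk(n2, j),
         pair_counts = cbind(pop1 = i, pop2 = j), gamma = gamma)
  })
}

#' Simulate a four-taxon site-pattern dataset for the D statistic
#'
#' Generates per-site bases for (H1, H2, H3, outgroup) with discordant
#' patterns at rates `P(ABBA) = q + delta`, `P(BABA) = q`; the remainder is
#' split between H3-only-derived sites and invariant sites. The expected
#' pooled D is `delta / (2q + delta)`.
#'
#' @param n_sites Number of sites.
#' @param q Baseline (incomplete lineage sorting) discordance rate per class
#'   (default 0.02).
#' @param delta Excess ABBA rate produced by gene flow (default 0 = null).
#' @param p_h3only Rate of sites where only H3 is derived (default 0.05).
#' @param spacing Base-pair distance between consecutive sites (default 1).
#' @param seed Optional RNG seed.
#' @return List with data frame `sites` (chrom, pos, b1, b2, b3, anc) and
#'   `expected_D`.
#' @export
sim_quartet <- function(n_sites, q = 0.02, delta = 0, p_h3only = 0.05,
                        spacing = 1, seed = NULL) {
  stopifnot(q >= 0, delta >= 0, q + delta + q + p_h3only <= 1)
  with_seed(seed, {
    pat <- sample.int(4L, n_sites, replace = TRUE,
                      prob = c(q + delta, q, p_h3only,
                               1 - (2 * q + delta + p_h3only)))
    anc_idx <- sample.int(4L, n_sites, replace = TRUE)
    der_idx <- ((anc_idx - 1L + sample.int(3L, n_sites, replace = TRUE)) %% 4L) + 1L
    anc <- BASES[anc_idx]
    der <- BASES[der_idx]
    b1 <- ifelse(pat == 2L, der, anc)           # BABA: H1 derived
    b2 <- ifelse(pat == 1L, der, anc)           # ABBA: H2 derived
    b3 <- ifelse(pat <= 3L, der, anc)           # derived in ABBA/BABA/H3-only
    list(sites = data.frame(chrom = "chr1",
                            pos = 1L + (seq_len(n_sites) - 1L) * spacing,
                            b1 = b1, b2 = b2, b3 = b3, anc = anc,
                            stringsAsFactors = FALSE),
         expected_D = if (2 * q + delta > 0) delta / (2 * q + delta) else 0)
  })
}

#' Genotype likelihoods for simulated data
#'
#' Applies the independent-reads likelihood model to a simulation's read
#' counts, polarized (ancestral, derived) so downstream SAF/SFS code can
#' consume the result directly. The error rate used is the one implied by
#' the emitted phred score, exactly as a pileup consumer would see it.
#'
#' @param sim A `sim_onepop` object.
#' @return Array sites x individuals x 3 of log genotype likelihoods.
#' @export
sim_gl3 <- function(sim) {
  gl3_from_counts(sim$counts, sim$anc, sim$der, phred_to_error(sim$phred))
}

#' Sample one base per site per individual from simulated counts
#'
#' @param sim A `sim_onepop` object.
#' @param seed Optional RNG seed.
#' @return Sites x individuals character matrix (NA where no reads).
#' @export
sim_sample_bases <- function(sim, seed = NULL) {
  with_seed(seed, {
    M <- sim$counts
    S <- dim(M)[1]
    I <- dim(M)[2]
    flat <- matrix(M, S * I, 4L)
    tot <- rowSums(flat)
    c1 <- flat[, 1]
    c2 <- c1 + flat[, 2]
    c3 <- c2 + flat[, 3]
    u <- stats::runif(S * I) * tot
    b <- 1L + (u > c1) + (u > c2) + (u > c3)
    b[tot == 0] <- NA_integer_
    matrix(BASES[b], S, I)
  })
}

#' Expand simulated counts to pileup sites
#'
#' Materializes a simulation as a list of [pileup_site] objects (all reads
#' carry the simulation's constant phred score), suitable for
#' [write_mpileup]. Intended for desk-scale fixtures.
#'
#' @param sim A `sim_onepop` object.
#' @return List of [pileup_site] objects.
#' @export
pileup_sites_from_sim <- function(sim) {
  S <- dim(sim$counts)[1]
  I <- dim(sim$counts)[2]
  lapply(seq_len(S), function(s) {
    reads <- lapply(seq_len(I), function(i) {
      b <- rep(BASES, times = sim$counts[s, i, ])
      list(base = b, qual = rep(sim$phred, length(b)))
    })
    pileup_site(chrom = sim$chrom[s], pos = sim$pos[s], ref = sim$anc[s],
                reads = reads, anc = sim$anc[s])
  })
}
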
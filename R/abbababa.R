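# ABBA-BABA / D-statistic from single sampled bases, with block partitioning
# and a weighted (uneven m-delete) block jackknife for standard errors.

#' Sample a single base from a read stack
#'
#' Draws one base uniformly among the reads passing the quality threshold.
#' Sampling a single base per site per individual removes the bias caused by
#' depth differences between samples.
#'
#' @param reads List with `base` and `qual` vectors.
#' @param min_baseQ Minimum phred quality (default 0).
#' @return A single base, or `NA_character_` if no read passes.
#' @export
sample_base <- function(reads, min_baseQ = 0) {
  b <- reads$base[reads$qual >= min_baseQ]
  if (!length(b)) return(NA_character_)
  b[sample.int(length(b), 1L)]
}

#' Classify a four-taxon site as ABBA, BABA or neither
#'
#' With the derived state defined against the outgroup/ancestral base `anc`:
#' ABBA means H1 carries the ancestral base and H2 and H3 share the derived
#' base; BABA means H2 is ancestral and H1 and H3 share the derived base.
#' Sites with more than two alleles among the four bases are discarded, as
#' are (optionally) transitions (`A/G`, `C/T`), which dominate post-mortem
#' damage in ancient DNA.
#'
#' @param b1,b2,b3 Sampled bases for H1, H2, H3 (vectors allowed).
#' @param anc Outgroup/ancestral base (vector allowed).
#' @param rm_trans Drop transition sites (default FALSE).
#' @return Character vector: `"ABBA"`, `"BABA"` or `"neither"`.
#' @export
classify_site <- function(b1, b2, b3, anc, rm_trans = FALSE) {
  stopifnot(!anyNA(c(b1, b2, b3, anc)))
  out <- rep("neither", length(b1))
  # biallelic check: every base must equal anc or one shared derived allele
  der <- ifelse(b1 != anc, b1, ifelse(b2 != anc, b2, b3))
  ok <- (b1 == anc | b1 == der) & (b2 == anc | b2 == der) &
    (b3 == anc | b3 == der) & der != anc
  if (rm_trans) ok <- ok & !is_transition(anc, der)
  abba <- ok & b1 == anc & b2 == der & b3 == der
  baba <- ok & b2 == anc & b1 == der & b3 == der
  out[abba] <- "ABBA"
  out[baba] <- "BABA"
  out
}

#' Aggregate classified sites into genomic blocks
#'
#' Blocks are `block_size`-base windows per chromosome (block index
#' `floor((pos - 1) / block_size)`); blocks without ABBA or BABA sites are
#' dropped. Jackknifing over blocks (rather than sites) respects linkage
#' between nearby sites.
#'
#' @param chrom,pos Site coordinates.
#' @param pattern Classification from [classify_site].
#' @param block_size Block length in bases (default 5e6).
#' @return Data frame with `chrom`, `block`, `nABBA`, `nBABA`.
#' @export
accumulate_blocks <- function(chrom, pos, pattern, block_size = 5e6) {
  stopifnot(block_size >= 1)
  keep <- pattern %in% c("ABBA", "BABA")
  if (!any(keep))
    return(data.frame(chrom = character(0), block = integer(0),
                      nABBA = integer(0), nBABA = integer(0)))
  chrom <- chrom[keep]
  blk <- (pos[keep] - 1) %/% block_size
  pat <- pattern[keep]
  key <- paste(chrom, blk, sep = "\r")
  ord <- !duplicated(key)
  out <- data.frame(chrom = chrom[ord], block = as.integer(blk[ord]),
                    nABBA = as.integer(tapply(pat == "ABBA", key, sum)[key[ord]]),
                    nBABA = as.integer(tapply(pat == "BABA", key, sum)[key[ord]]))
  rownames(out) <- NULL
  out
}

#' Pooled D statistic
#'
#' `D = (nABBA - nBABA) / (nABBA + nBABA)`.
#'
#' @param nABBA,nBABA Pattern counts.
#' @return D in `[-1, 1]`.
#' @export
dstat <- function(nABBA, nBABA) {
  tot <- nABBA + nBABA
  if (tot <= 0) stop("D statistic undefined: no ABBA or BABA sites")
  (nABBA - nBABA) / tot
}

#' Weighted block jackknife for the D statistic
#'
#' Computes the pooled D and a weighted delete-one-block (uneven m-delete)
#' jackknife with block weight `m_b = nABBA_b + nBABA_b`: with `h_b = n /
#' m_b` and leave-one-out estimates `D_(-b)`, the bias-corrected estimate is
#' `B D - sum_b (1 - m_b/n) D_(-b)` and the variance is `(1/B) sum_b
#' (pseudo_b - jackEst)^2 / (h_b - 1)` with pseudovalues `pseudo_b = h_b D -
#' (h_b - 1) D_(-b)`. For equal-weight blocks this reduces exactly to the
#' classical delete-1 jackknife. `Z = D / SE`.
#'
#' @param blocks Data frame with `nABBA` and `nBABA` per block (see
#'   [accumulate_blocks]).
#' @return List with `nABBA`, `nBABA`, `D`, `jackEst`, `SE`, `Z`,
#'   `n_blocks`.
#' @export
dstat_jackknife <- function(blocks) {
  blocks <- blocks[blocks$nABBA + blocks$nBABA > 0, , drop = FALSE]
  B <- nrow(blocks)
  if (B < 2L) stop("weighted jackknife requires at least 2 non-empty blocks")
  A <- sum(blocks$nABBA)
  Bb <- sum(blocks$nBABA)
  D <- dstat(A, Bb)
  m <- blocks$nABBA + blocks$nBABA
  n <- sum(m)
  loo <- ((A - blocks$nABBA) - (Bb - blocks$nBABA)) /
    ((A - blocks$nABBA) + (Bb - blocks$nBABA))
  if (anyNA(loo) || any(!is.finite(loo)))
    stop("a block contains all ABBA/BABA sites; cannot jackknife")
  h <- n / m
  jack_est <- B * D - sum((1 - m / n) * loo)
  pseudo <- h * D - (h - 1) * loo
  var_j <- mean((pseudo - jack_est)^2 / (h - 1))
  se <- sqrt(var_j)
  list(nABBA = A, nBABA = Bb, D = D, jackEst = jack_est, SE = se,
       Z = D / se, n_blocks = B)
}

#' D statistics for all triples of individuals
#'
#' Given one sampled base per individual per site and the outgroup base,
#' computes the blocked jackknife D statistic for every ordered triple
#' (H1, H2, H3) of distinct individuals, in lexicographic index order.
#' Since swapping H1 and H2 only flips the sign of D, `unique_pairs = TRUE`
#' keeps one ordering per {H1, H2} set (the Table-style reduced listing).
#'
#' @param bases Sites x individuals character matrix of sampled bases
#'   (NA = missing); column names label the individuals.
#' @param anc Outgroup/ancestral base per site (NA allowed; such sites are
#'   skipped).
#' @param chrom,pos Site coordinates (defaults `"chr1"`, `1:S`).
#' @param block_size Jackknife block length (default 5e6).
#' @param rm_trans Drop transition sites (default FALSE).
#' @param unique_pairs Suppress sign-redundant (H2, H1) rows (default
#'   FALSE, i.e. all ordered triples).
#' @return Data frame with columns H1, H2, H3, nABBA, nBABA, Dstat, jackEst,
#'   SE, Z.
#' @export
all_triples <- function(bases, anc, chrom = NULL, pos = NULL,
                        block_size = 5e6, rm_trans = FALSE,
                        unique_pairs = FALSE) {
  bases <- as.matrix(bases)
  S <- nrow(bases)
  K <- ncol(bases)
  stopifnot(K >= 3L, length(anc) == S)
  if (is.null(pos)) pos <- seq_len(S)
  if (is.null(chrom)) chrom <- rep("chr1", S)
  ids <- colnames(bases)
  if (is.null(ids)) ids <- paste0("Ind", seq_len(K) - 1L)
  rows <- list()
  for (i1 in seq_len(K)) for (i2 in seq_len(K)) for (i3 in seq_len(K)) {
    if (length(unique(c(i1, i2, i3))) != 3L) next
    if (unique_pairs && i1 > i2) next
    use <- !is.na(anc) & !is.na(bases[, i1]) & !is.na(bases[, i2]) &
      !is.na(bases[, i3])
    pat <- classify_site(bases[use, i1], bases[use, i2], bases[use, i3],
                         anc[use], rm_trans = rm_trans)
    blocks <- accumulate_blocks(chrom[use], pos[use], pat, block_size)
    jk <- dstat_jackknife(blocks)
    rows[[length(rows) + 1L]] <- data.frame(
      H1 = ids[i1], H2 = ids[i2], H3 = ids[i3],
      nABBA = jk$nABBA, nBABA = jk$nBABA, Dstat = jk$D,
      jackEst = jk$jackEst, SE = jk$SE, Z = jk$Z)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
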
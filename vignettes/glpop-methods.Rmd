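---
title: "Methods: genotype-likelihood population genetics at low coverage"
author: "glpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-likelihood population genetics at low coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Why genotype likelihoods

At 2–4X coverage a diploid genotype cannot be called reliably: a
heterozygote sampled twice shows both alleles only half the time, and
sequencing errors masquerade as rare alleles. Every method in glpop
therefore works on **genotype likelihoods** (GLs) — the probability of an
individual's read stack given each possible genotype — and integrates over
genotype uncertainty instead of fixing a call. GLs are defined up to a
per-site constant throughout; every downstream estimator in the package is
invariant to per-individual rescaling (this is asserted by tests).

## Genotype likelihood models

For a read stack with bases $b_r$ and phred qualities $q_r$,
$\varepsilon_r = \min(10^{-q_r/10}, 0.75)$ (the cap marks a base as
uninformative on a 4-letter alphabet and keeps $1-\varepsilon$ positive),
the independent-reads model is

$$\log L(A_1A_2) = \sum_r \log\left(\tfrac12 P(b_r\mid A_1) +
\tfrac12 P(b_r\mid A_2)\right),\qquad
P(b\mid A)=\begin{cases}1-\varepsilon_r & b=A\\ \varepsilon_r/3 &
\text{otherwise.}\end{cases}$$

`gl10_gatk()` evaluates all 10 unordered genotypes (fixed alphabetical
order AA, AC, …, TT shared by every module). `gl10_type_specific()`
replaces $P(b\mid A)$ with a 4×4 error matrix $E[A,b]$, which reproduces
the independent-reads model exactly when $E$ is symmetric with
off-diagonals $\varepsilon/3$ — a model-equivalence used as a test oracle.
Two published GL variants that depend on recalibration machinery defined
outside this package's scope (SOAPsnp-style and SAMtools/Maq-style) are
deliberately not implemented; the CLI's `-GL` flag accepts only `2`
(independent reads) and `4` (type-specific) and fails informatively
otherwise.

The major/minor allele pair is inferred by brute force over the six
diallelic pairs, scoring each pair by the summed log-likelihood under a
uniform within-pair genotype prior; the major allele is the one with the
larger expected count, ties alphabetical.

## Allele frequencies and SNP discovery

With diallelic GLs $L_i(g)$ and the HWE prior
$((1-f)^2,\,2f(1-f),\,f^2)$, `estimate_maf_em()` runs the classic
gene-counting EM: the update is the mean posterior allele dosage. Defaults:
start $f=0.1$, stop at $|f'-f|<10^{-8}$ or 200 iterations. Because EM only
approaches the boundaries asymptotically — and because for arbitrary
(non-read-derived) likelihood fixtures the mixture likelihood can have a
boundary global maximum the interior iteration misses — the converged value
is compared against $f=0$ and $f=1$ and the likelihood argmax is returned.
Individuals with flat GL rows (no reads) are excluded from the individual
count.

`snp_lrt()` tests site variability with $\mathrm{LRT} = 2(\ell(\hat f) -
\ell(0))$ against $\chi^2_1$. The null sits on the boundary of the
parameter space, so the plain $\chi^2_1$ reference is conservative; the
half-mixture $\tfrac12\chi^2_0+\tfrac12\chi^2_1$ is available via
`boundary_mix = TRUE`. The default is the conservative choice because the
test's main use is SNP discovery, where false positives are the costly
error. `case_control_lrt()` compares group-specific frequency fits against
a pooled fit (2 log-likelihood-ratio, $\chi^2_1$); with certain genotypes
it collapses to the classical 2×2 allele-count G-test, the test oracle.

## Sample allele frequency likelihoods

The SAF vector at a site is $p(X \mid D=j)$, the probability of all
individuals' reads given $j$ derived alleles in the sample,
$j = 0,\dots,2n$. With GLs polarized by the ancestral allele it is computed
by the dynamic programme

$$h_0 = [1],\qquad h_k(j) = \sum_{g\in\{0,1,2\}} h_{k-1}(j-g)\,L_k(g)\,w(g),
\qquad w = (1,2,1),$$

with $p(X\mid D=j) = h_n(j)/\binom{2n}{j}$. The convolution is carried
entirely in log space (element-wise log-sum-exp with a running maximum
shift), so stacks of hundreds of individuals with extreme likelihood spans
cannot under- or overflow. Each site's vector is normalized to maximum 0;
this per-site constant is irrelevant to all downstream likelihoods.
`saf_all_sites()` runs the same recursion with a sites × classes matrix as
state and is tested for exact agreement with the per-site version;
exhaustive enumeration over all $3^n$ genotype configurations is the
correctness oracle for $n \le 4$.

## SFS estimation by EM

The spectrum $\gamma$ is a probability vector (1D) or matrix (2D joint)
over derived-allele counts. The per-site likelihood is the mixture
$\sum_j \gamma_j\, p(X_s\mid D=j)$ (respectively
$\sum_{ij}\gamma_{ij}\,p(X^1_s\mid i)\,p(X^2_s\mid j)$ for two populations
on their shared sites), and both `sfs_em_1d()` and `sfs_em_2d()` iterate
the standard mixture-weight EM

$$\gamma'_{ij} = \frac1N \sum_s
\frac{\gamma_{ij}\, p(X^1_s\mid i)\, p(X^2_s\mid j)}
{\sum_{kl}\gamma_{kl}\, p(X^1_s\mid k)\, p(X^2_s\mid l)}.$$

Some presentations of this update omit the $\gamma^{old}$ factor and the
$1/N$ normalization; the form above is implemented because it is the EM
for this mixture — the log-likelihood provably never decreases (asserted at
every iteration in the tests) and certain data reproduce the empirical
histogram exactly. Initialization is the uniform spectrum (mixture-weight
EM has no label-switching ambiguity); convergence is a relative
log-likelihood gain below `tol` (default 1e-8) or `max_iter` (default
500). Two-population sites are intersected by exact (chromosome, position)
match, and estimation refuses to run on an empty intersection.

### What recovery can and cannot achieve at 2X

The package's simulation studies use 5×10⁴ sites at 2X depth with 0.2%
base error (the conditions of the original low-coverage simulation study
this machinery targets; run by `scripts/acceptance.R` and the acceptance
tests). Under these conditions the 1D spectrum for 10 diploids is
recovered to total-variation distance below 0.05. The 2D joint spectrum is
a much harder target: 169 cells for 6+6 diploids, each site carrying only
fractional-read information per individual. Its *marginals* are recovered
about as well as the 1D spectrum (TV ≈ 0.03), and with near-certain data
the estimate matches the empirical 2D histogram to numerical precision,
but the converged ML joint estimate at 2X spreads mass along weakly
identified directions: its TV from the generating spectrum is ≈ 0.10 for a
strongly correlated truth and worse for a product-form truth, and running
the EM longer does not shrink it (it is estimator variance at the ML
optimum, not incomplete convergence). Users should treat desk-scale 2D
estimates as qualitative and rely on marginals, or use more sites.

## Genotype posteriors and calling

Three priors: uniform (`posterior_uniform`, the normalized likelihood),
population-frequency HWE (`posterior_af`), and the sample-wide SFS
(`posterior_sfs`), which conditions individual $i$ on everyone else's
reads:

$$P(G_i=g\mid X,\gamma) \propto L_i(g)\,w(g)\sum_j
\frac{\gamma_j\, h^{(-i)}(j-g)}{\binom{2n}{j}},$$

with $h^{(-i)}$ the SAF convolution excluding $i$. The leave-one-out
convolutions are recomputed per individual ($O(n^2)$ per site) instead of
divided out, which is numerically safe and cheap at desk scale; exhaustive
enumeration for $n=3$ is the oracle. `call_genotypes()` takes the
posterior argmax, breaking ties toward the lower genotype index
(determinism), and masks calls whose posterior falls below the cutoff.

## ABBA-BABA D statistics

One base is sampled uniformly per site per individual (`sample_base`),
which removes depth bias between samples. With outgroup base defining the
derived state, ABBA means H1 ancestral with H2 = H3 derived, BABA the
mirror image; sites with a third allele are discarded, and `rm_trans`
additionally drops A/G and C/T polymorphisms (post-mortem damage in
ancient DNA). $D = (n_{ABBA}-n_{BABA})/(n_{ABBA}+n_{BABA})$.

Standard errors come from a weighted delete-one-block jackknife over
`block_size` windows (default 5 Mb), with block weight
$m_b = n_{ABBA,b}+n_{BABA,b}$, pseudovalues
$h_b\hat D - (h_b-1)\hat D_{(-b)}$, $h_b = n/m_b$, and the bias-corrected
estimate $B\hat D - \sum_b (1-m_b/n)\hat D_{(-b)}$. For equal-weight
blocks this reduces *exactly* to the classical delete-1 jackknife (tested
to 1e-12). $Z = D/\mathrm{SE}$ uses the pooled $D$ rather than the
bias-corrected estimate; the two agree to the printed precision in
practice, so the choice is immaterial but documented. `all_triples()`
emits every ordered (H1, H2, H3) triple by default; since swapping H1/H2
only flips the sign, `unique_pairs = TRUE` gives the reduced half-listing
some published tables use.

## Error-rate estimation

Three estimators, all consuming one sampled base per site per individual
(the same depth-bias-free sampling as the D statistic): raw outgroup
mismatch rates (`mismatch_matrix`); calibration against a high-quality
individual (`calibrated_error`), which treats the high-quality individual's
mismatch rates as true divergence $P$ and fits the sample's counts with
the composition $P E$ by multinomial maximum likelihood over row-stochastic
$E$ (BFGS on per-row logits, relative tolerance 1e-12; first-order model,
no back-mutation — adequate at percent-scale rates; rows with no
observations return identity with a warning); and a joint EM
(`joint_error_freq_em`) that alternates genotype/transmitted-allele
posteriors with closed-form updates of per-site frequencies and the error
matrix, so the observed-data likelihood is monotone. Major/minor alleles
are fixed from raw counts before the joint EM starts and not revisited,
keeping the updates a single well-defined EM.

## The simulator

`sim_onepop()` draws per-site derived counts from a configured spectrum,
assigns them to individuals by hypergeometric (permutation) sampling —
so the realized sample-count distribution *is* the configured spectrum,
matching the definition of what the SFS estimators recover — then draws
Poisson(`depth`) reads per individual and flips each read to each wrong
base with probability `err`/3. The emitted phred score is the one implied
by `err`. Defaults are the study conditions: depth 2, error 0.002. The
default spectrum (`neutral_sfs`) is the neutral 1/j shape over segregating
classes with an invariant-site mass of 0.2 — polymorphism-enriched
relative to genome-wide resequencing data, a deliberate choice so that
spectrum-recovery tests exercise all allele-frequency classes rather than
being dominated by the invariant class. `shared_drift_sfs2d()` builds the
correlated two-population spectrum of a recent split (both samples
binomial around a shared ancestral frequency); `sim_twopop()` draws
aligned two-population data from any joint spectrum; `sim_quartet()`
generates four-taxon site patterns with controllable discordance
(`q`) and gene-flow excess (`delta`), with expected
$D = \delta/(2q+\delta)$.

The simulator deliberately matches the GL models' error model so that
recovery tests isolate estimator error. It does **not** emulate linkage,
recombination, realistic quality-score distributions, mapping error,
indels, or reference bias; passing recovery tests therefore demonstrate
estimator correctness under the model, not robustness to real-data
artifacts. Everything is seedable (`seed` arguments restore the caller's
RNG state) and byte-reproducible.

## Degenerate inputs and tie-breaking

Empty read stacks give flat (all-zero) log-GLs and are excluded from
individual counts; a site where every individual is empty is an error for
frequency estimation. Zero aligned sites is an error for the 2D EM. A
jackknife needs at least two non-empty blocks, and a block holding *all*
informative sites is rejected. Posterior ties call the lower genotype
index; major/minor ties break alphabetically. `cutoff = 0` disables
call missingness.

## Problem sizes

The test suite and acceptance script run, on one CPU in about three
minutes total: 5×10⁴-site spectrum recoveries (1D and 2D), a 10⁴-site
boundary-null calibration of the SNP test, 200 null-quartet jackknife
replicates, 100-fixture enumeration oracles for the SAF recursion
(n ≤ 4) and SFS-prior posteriors (n = 3), and the desk-scale end-to-end
pileup workflow.
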
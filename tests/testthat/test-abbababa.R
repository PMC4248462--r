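# ABBA-BABA D statistics, block partitioning and weighted jackknife

test_that("single-base sampling is uniform over passing reads", {
  expect_equal(sample_base(list(base = "G", qual = 30)), "G")
  expect_true(is.na(sample_base(list(base = character(0), qual = numeric(0)))))
  expect_true(is.na(sample_base(list(base = c("A", "G"), qual = c(10, 10)),
                                min_baseQ = 30)))
  set.seed(18)
  rd <- list(base = c("A", "A", "A", "G"), qual = rep(30, 4))
  freq <- mean(replicate(1e4, sample_base(rd)) == "G")
  expect_equal(freq, 0.25, tolerance = 0.08)  # +- 2 sd of binomial noise
})

test_that("site patterns classify as ABBA/BABA with biallelic and transition filters", {
  expect_equal(classify_site("A", "G", "G", "A"), "ABBA")
  expect_equal(classify_site("G", "A", "G", "A"), "BABA")
  expect_equal(classify_site("A", "C", "G", "A"), "neither")  # triallelic
  expect_equal(classify_site("A", "A", "A", "A"), "neither")  # invariant
  expect_equal(classify_site("A", "A", "G", "A"), "neither")  # H3-only derived
  expect_equal(classify_site("A", "G", "G", "A", rm_trans = TRUE), "neither")
  expect_equal(classify_site("A", "C", "C", "A", rm_trans = TRUE), "ABBA")
  expect_equal(classify_site(c("A", "G"), c("G", "A"), c("G", "G"),
                             c("A", "A")), c("ABBA", "BABA"))
})

test_that("block accumulation uses floor((pos-1)/size) per chromosome", {
  pat <- rep(c("ABBA", "BABA", "neither"), c(3, 2, 2))
  pos <- c(1, 100, 100, 101, 150, 2, 3)
  out <- accumulate_blocks(rep("chr1", 7), pos, pat, block_size = 100)
  expect_equal(out$block, c(0L, 1L))
  expect_equal(out$nABBA, c(3L, 0L))
  expect_equal(out$nBABA, c(0L, 2L))
  # boundary: pos = size -> block 0; pos = size + 1 -> block 1
  out <- accumulate_blocks(c("chr1", "chr1"), c(100, 101), c("ABBA", "ABBA"),
                           block_size = 100)
  expect_equal(out$block, c(0L, 1L))
  # chromosomes are separate blocks; empty blocks dropped
  out <- accumulate_blocks(c("chr1", "chr2"), c(5, 5), c("ABBA", "neither"),
                           block_size = 100)
  expect_equal(nrow(out), 1)
  expect_equal(out$chrom, "chr1")
})

test_that("pooled D reproduces the published worked examples", {
  expect_equal(round(dstat(355539, 360029), 2), -0.01)
  expect_equal(round(dstat(286551, 90667), 2), 0.52)
  expect_equal(round(dstat(103016, 90667), 2), 0.06)
  expect_equal(round(dstat(286551, 103016), 2), 0.47)
})

test_that("weighted jackknife reduces to the classical delete-1 oracle", {
  set.seed(27)
  # equal-information blocks: nABBA + nBABA constant across blocks
  B <- 12
  nab <- rbinom(B, 400, 0.5)
  blocks <- data.frame(chrom = "chr1", block = 0:(B - 1),
                       nABBA = nab, nBABA = 400 - nab)
  jk <- dstat_jackknife(blocks)
  oracle <- delete1_jackknife_oracle(blocks$nABBA, blocks$nBABA)
  expect_equal(jk$D, oracle$D, tolerance = 1e-12)
  expect_equal(jk$jackEst, oracle$jackEst, tolerance = 1e-12)
  expect_equal(jk$SE, oracle$SE, tolerance = 1e-12)
  expect_equal(jk$Z, jk$D / jk$SE)
  expect_error(dstat_jackknife(blocks[1, ]), "at least 2")
})

test_that("D is antisymmetric in H1/H2 and all triples are enumerated", {
  sim <- sim_quartet(4000, q = 0.05, delta = 0.02, seed = 31)
  st <- sim$sites
  bases <- cbind(A = st$b1, B = st$b2, C = st$b3)
  tab <- all_triples(bases, st$anc, chrom = st$chrom, pos = st$pos,
                     block_size = 500)
  expect_equal(nrow(tab), 6)  # 3 * 2 * 1 ordered triples
  r12 <- tab[tab$H1 == "A" & tab$H2 == "B" & tab$H3 == "C", ]
  r21 <- tab[tab$H1 == "B" & tab$H2 == "A" & tab$H3 == "C", ]
  expect_equal(r12$Dstat, -r21$Dstat, tolerance = 1e-12)
  expect_equal(r12$SE, r21$SE, tolerance = 1e-12)
  expect_equal(r12$nABBA, r21$nBABA)
  # reduced listing halves the rows
  tab_u <- all_triples(bases, st$anc, chrom = st$chrom, pos = st$pos,
                       block_size = 500, unique_pairs = TRUE)
  expect_equal(nrow(tab_u), 3)
  # 5 individuals -> 60 ordered, 30 reduced (independent presence/absence
  # of a shared derived allele, so every triple is informative)
  set.seed(35)
  bases5 <- matrix(ifelse(runif(4000 * 5) < 0.12, "G", "A"), 4000, 5,
                   dimnames = list(NULL, c("A", "B", "C", "D", "E")))
  anc5 <- rep("A", 4000)
  expect_equal(nrow(all_triples(bases5, anc5, pos = 1:4000,
                                block_size = 2000)), 60)
  expect_equal(nrow(all_triples(bases5, anc5, pos = 1:4000,
                                block_size = 2000, unique_pairs = TRUE)), 30)
})

test_that("introgression inflates D and Z grows with site count", {
  simA <- sim_quartet(20000, q = 0.02, delta = 0.01, seed = 61)
  stA <- simA$sites
  patA <- classify_site(stA$b1, stA$b2, stA$b3, stA$anc)
  jkA <- dstat_jackknife(accumulate_blocks(stA$chrom, stA$pos, patA, 1000))
  expect_gt(jkA$D, 0)
  # within 3 jackknife SEs of the generative expectation
  expect_lt(abs(jkA$D - simA$expected_D), 3 * jkA$SE)
  simB <- sim_quartet(80000, q = 0.02, delta = 0.01, seed = 62)
  stB <- simB$sites
  patB <- classify_site(stB$b1, stB$b2, stB$b3, stB$anc)
  jkB <- dstat_jackknife(accumulate_blocks(stB$chrom, stB$pos, patB, 1000))
  expect_gt(jkB$Z, jkA$Z * 1.2)  # Z scales roughly with sqrt(sites)
})

test_that("quartet simulation hits its target D at scale", {
  # delta chosen for E[D] = 0.2: delta = 2 q D / (1 - D)
  q <- 0.02
  delta <- 2 * q * 0.2 / (1 - 0.2)
  sim <- sim_quartet(1e5, q = q, delta = delta, seed = 71)
  st <- sim$sites
  pat <- classify_site(st$b1, st$b2, st$b3, st$anc)
  expect_equal(sim$expected_D, 0.2, tolerance = 1e-12)
  expect_equal(dstat(sum(pat == "ABBA"), sum(pat == "BABA")), 0.2,
               tolerance = 0.15)
})
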
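# Allele frequencies (diploid and multicopy counting), rarefaction,
# heterozygosity, sequence diversity and APD.

test_that("multicopy and diploid counting rules", {
  gt <- toy_gt(list("A", c("A", "B")), kind = "sequence_multicopy",
               locus = "dqa")
  pm <- setNames(rep("E", 2), gt$individuals)
  sp <- allele_frequencies(gt, pm, "dqa", "E", mode = "multicopy")
  expect_equal(unname(sp$counts[c("A", "B")]), c(3, 1))
  expect_equal(unname(sp$freqs[c("A", "B")]), c(0.75, 0.25))

  gt2 <- toy_gt(rep(list(c("a", "a")), 10))
  pm2 <- setNames(rep("E", 10), gt2$individuals)
  sp2 <- allele_frequencies(gt2, pm2, "L1", "E")
  expect_equal(sp2$n, 20)
  expect_equal(unname(sp2$freqs), 1)

  # half-locus call adds one copy of the scored allele
  gt3 <- toy_gt(list(c("a", "b"), c("a", NA)))
  pm3 <- setNames(rep("E", 2), gt3$individuals)
  sp3 <- allele_frequencies(gt3, pm3, "L1", "E")
  expect_equal(sp3$n, 3)
  expect_equal(unname(sp3$counts["a"]), 2)

  expect_error(allele_frequencies(gt2, pm2, "L1", "nope"), "empty")
})

test_that("rarefied richness: identity, enumeration oracle, monotonicity", {
  counts <- c(A = 3, B = 1)
  # exhaustive: all C(4,2)=6 subsamples of 2 copies -> mean distinct = 1.5
  copies <- rep(names(counts), counts)
  pairs <- combn(4, 2)
  expected <- mean(apply(pairs, 2, function(i)
    length(unique(copies[i]))))
  expect_equal(expected, 1.5)
  expect_equal(allelic_richness_rarefied(counts, 2), 1.5)

  expect_equal(allelic_richness_rarefied(counts, 4), 2)   # g = n -> A
  expect_equal(allelic_richness_rarefied(counts, 1), 1)   # g = 1 exactly 1

  set.seed(3)
  cnt <- c(a = 17, b = 9, c = 5, d = 1)
  ag <- vapply(1:32, function(g) allelic_richness_rarefied(cnt, g), 0)
  expect_true(all(diff(ag) >= -1e-12))
  expect_equal(ag[32], 4)
  expect_equal(ag[1], 1)

  expect_error(allelic_richness_rarefied(counts, 5), "g must lie")
})

test_that("heterozygosity: plain, unbiased and observed", {
  gt <- toy_gt(list(c("a", "b"), c("a", "a"), c("b", "b"), c("a", "b")))
  pm <- setNames(rep("E", 4), gt$individuals)
  sp <- allele_frequencies(gt, pm, "L1", "E")
  h <- heterozygosity(sp, gt$calls$L1)
  expect_equal(h$H_E, 0.5)
  expect_equal(h$H_E_unbiased, 0.5 * 8 / 7)
  expect_equal(h$H_O, 0.5)

  mono <- allele_frequencies(toy_gt(rep(list(c("a", "a")), 3)),
                             setNames(rep("E", 3),
                                      sprintf("ind%03d", 1:3)), "L1", "E")
  expect_equal(heterozygosity(mono)$H_E, 0)

  # n = 2 copies, two distinct alleles: unbiased correction gives 1
  two <- toy_gt(list(c("a", "b")))
  sp2 <- allele_frequencies(two, setNames("E", "ind001"), "L1", "E")
  expect_equal(heterozygosity(sp2)$H_E_unbiased, 1)
})

test_that("sequence diversity statistics and their closed forms", {
  L <- 100
  s1 <- strrep("A", L)
  s2 <- paste0(strrep("A", 99), "C")
  aln <- locus_alignment("x", c("h1", "h2"), c(s1, s2))
  st <- seq_diversity_stats(aln, c("h1", "h2"))
  expect_equal(st$S, 1); expect_equal(st$k, 1)
  expect_equal(st$pi, 0.01); expect_equal(st$H_D, 1)
  expect_equal(st$pi * st$analyzed_sites, st$k)

  same <- seq_diversity_stats(aln, c("h1", "h1", "h1"))
  expect_equal(same$S, 0); expect_equal(same$k, 0)
  expect_equal(same$H_D, 0); expect_equal(same$pi, 0)

  # 4 copies, two haplotypes at 2:2 -> H_D = (4/3)(1 - 0.5) = 2/3
  st4 <- seq_diversity_stats(aln, c("h1", "h1", "h2", "h2"))
  expect_equal(st4$H_D, 2 / 3)

  # indel columns excluded from nucleotide stats, kept in allele identity
  g1 <- paste0(strrep("A", 90), strrep("-", 10))
  aln2 <- locus_alignment("y", c("h1", "h2", "h3"), c(s1, s2, g1))
  expect_equal(aln2$analyzed_sites, 90)
  st2 <- seq_diversity_stats(aln2, c("h1", "h3"))
  expect_equal(st2$k, 0)          # identical over analyzed columns
  expect_equal(st2$H_D, 1)        # but distinct alleles by gap pattern
})

test_that("bootstrap SD of sequence diversity is available over individuals", {
  set.seed(5)
  sc <- sim_scenario(N_e = 60L, n_per_pop = c(15L, 15L))
  r <- simulate_seq_two_pop(sc, "intron", seed = 6, n_demes = 1)
  cbi <- split(r$copies, rep(seq_len(15), each = 2))
  st <- seq_diversity_stats(r$alignment, r$copies, n_boot = 100,
                            copies_by_individual = cbi, seed = 7)
  expect_true(st$H_D_sd_boot > 0 && st$pi_sd_boot > 0)
  # analytic and bootstrap SDs agree in order of magnitude
  expect_lt(st$H_D_sd_boot / st$H_D_sd, 4)
  expect_gt(st$H_D_sd_boot / st$H_D_sd, 1 / 4)
})

test_that("APD equals 100*(1 - mean Dice) and matches a brute-force loop", {
  gt <- toy_gt(list(c("a", "a"), c("a", "a"), c("a", "a")))
  pm <- setNames(rep("E", 3), gt$individuals)
  expect_equal(apd(gt, pm, "L1", "E")$APD, 0)

  gt2 <- toy_gt(list(c("a", "b"), c("c", "d")))
  pm2 <- setNames(rep("E", 2), gt2$individuals)
  expect_equal(apd(gt2, pm2, "L1", "E")$APD, 100)

  # pair count identity C = N(N-1)/2 and vectorized == brute force
  set.seed(9)
  sets <- replicate(36, sample(letters[1:6], sample(1:4, 1)),
                    simplify = FALSE)
  gt3 <- toy_gt(sets, kind = "sequence_multicopy", locus = "dqa")
  pm3 <- setNames(rep("E", 36), gt3$individuals)
  row <- apd(gt3, pm3, "dqa", "E")
  expect_equal(row$C, 36 * 35 / 2)
  expect_equal(row$C, 630)
  brute <- c()
  for (i in 1:35) for (j in (i + 1):36) {
    x <- sets[[i]]; y <- sets[[j]]
    shared <- sum(!is.na(match(x, y)))  # distinct ids here, match is safe
    brute <- c(brute, 100 * (1 - 2 * shared / (length(x) + length(y))))
  }
  expect_equal(row$APD, mean(brute), tolerance = 1e-12)
  expect_equal(row$SE, sd(brute) / sqrt(630), tolerance = 1e-12)

  # empty individuals are excluded with a warning
  gt4 <- toy_gt(list(c("a", "b"), character(0), c("a", "a")))
  pm4 <- setNames(rep("E", 3), gt4$individuals)
  expect_warning(row4 <- apd(gt4, pm4, "L1", "E"), "excluded")
  expect_equal(row4$N, 2)
})

test_that("diversity table lays out per-population rows with rarefaction", {
  set.seed(10)
  sc <- sim_scenario(N_e = 60L, n_per_pop = c(10L, 8L))
  r <- simulate_seq_two_pop(sc, "intron", seed = 11)
  tab <- diversity_table(r$genotypes, r$popmap)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$A_CORR <= tab$A + 1e-9))
  # rarefaction size is the smaller population's copy count: equality there
  smaller <- which.min(tab$n_copies)
  expect_equal(tab$A_CORR[smaller], tab$A[smaller])
  expect_equal(tab$pi, tab$k / (668 - tab$indel_bp), tolerance = 1e-12)
})
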
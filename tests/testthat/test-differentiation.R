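# F_ST (Weir-Cockerham), K2P distances, AMOVA Phi_ST, Jost's D_est, the
# similarity-based F' and the Markov-chain exact test.

test_that("Weir-Cockerham theta: limits and a direct-formula oracle", {
  # two populations fixed for different alleles
  g1 <- replicate(50, c("1", "1"), simplify = FALSE)
  g2 <- replicate(50, c("2", "2"), simplify = FALSE)
  gt <- toy_gt(c(g1, g2))
  fst <- wc_fst(gt, toy_popmap(gt, 50), n_boot = 0, n_perm = 0)
  expect_gt(fst$theta, 0.98)

  # 3-individual toy vs the independently coded variance components
  toy <- toy_gt(list(c("1", "2"), c("1", "1"), c("2", "3")))
  pm <- setNames(c("A", "A", "B"), toy$individuals)
  fst_toy <- wc_fst(toy, pm, n_boot = 0, n_perm = 0)
  by_pop <- list(rbind(c("1", "2"), c("1", "1")), rbind(c("2", "3")))
  expect_equal(fst_toy$theta, oracle_wc_theta(by_pop), tolerance = 1e-12)

  # random halves of one panmictic pool: theta centred at 0
  set.seed(31)
  th <- replicate(60, {
    g <- replicate(40, sample(as.character(1:6), 2, TRUE),
                   simplify = FALSE)
    gt0 <- toy_gt(g)
    wc_fst(gt0, toy_popmap(gt0, 20), n_boot = 0, n_perm = 0)$theta
  })
  expect_lt(abs(mean(th)), 0.02)

  # permutation p is significant for the fixed-difference case
  fst_p <- wc_fst(gt, toy_popmap(gt, 50), n_boot = 100, n_perm = 99,
                  seed = 5)
  expect_lte(fst_p$p, 0.02)
})

test_that("K2P distance closed forms and agreement with ape", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # 1 transition in 4 sites: P = 0.25, Q = 0
  expect_equal(k2p_distance("ACGT", "GCGT"), -0.5 * log(0.5),
               tolerance = 1e-12)
  # 2 transversions in 4 sites: Q = 0.5 saturates
  expect_equal(k2p_distance("ACGT", "CCGA"), Inf)

  set.seed(33)
  for (i in 1:5) {
    s1 <- sample(c("A", "C", "G", "T"), 200, TRUE)
    s2 <- s1
    mut <- sample(200, 20)
    s2[mut] <- sapply(s2[mut], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1))
    d_ape <- as.numeric(ape::dist.dna(ape::as.DNAbin(
      rbind(a = tolower(s1), b = tolower(s2))), model = "K80"))
    expect_equal(k2p_distance(paste(s1, collapse = ""),
                              paste(s2, collapse = "")),
                 d_ape, tolerance = 1e-9)
  }
})

test_that("AMOVA Phi_ST: limits, 6-copy oracle, identity = haplotype F_ST", {
  aln <- locus_alignment("s", c("h1", "h2", "h3"),
                         c(strrep("A", 40),
                           paste0(strrep("A", 30), strrep("C", 10)),
                           paste0(strrep("G", 5), strrep("A", 35))))
  # populations fixed for haplotypes 10 substitutions apart
  calls <- c(rep(list("h1"), 6), rep(list("h2"), 6))
  gt <- toy_gt(calls, kind = "sequence_diploid", locus = "s",
               alignments = list(s = aln))
  pm <- toy_popmap(gt, 6)
  ph <- phi_st_amova(gt, pm, "s", "K2P", n_perm = 0)
  expect_gt(ph$phi_st, 0.99)

  # identical haplotype spectra -> Phi_ST ~ 0
  calls2 <- rep(list("h1", "h2", c("h1", "h2")), 4)
  gt2 <- toy_gt(calls2, kind = "sequence_diploid", locus = "s",
                alignments = list(s = aln))
  ph2 <- phi_st_amova(gt2, toy_popmap(gt2, 6), "s", "K2P", n_perm = 99,
                      seed = 3)
  expect_lt(abs(ph2$phi_st), 0.2)
  expect_gt(ph2$p, 0.2)

  # 6-copy example against the double-loop sums-of-squares oracle
  set.seed(35)
  calls3 <- list(c("h1", "h2"), "h3", c("h2", "h3"))
  gt3 <- toy_gt(calls3, kind = "sequence_diploid", locus = "s",
                alignments = list(s = aln))
  pm3 <- setNames(c("A", "A", "B"), gt3$individuals)
  ph3 <- phi_st_amova(gt3, pm3, "s", "K2P", n_perm = 0)
  d2 <- k2p_matrix(aln)
  copies <- c("h1", "h2", "h3", "h3", "h2", "h3")
  labs <- c("A", "A", "A", "A", "B", "B")
  expect_equal(ph3$phi_st, oracle_amova_phi(copies, labs, d2),
               tolerance = 1e-10)

  # identity distance equals haplotype-frequency F_ST from the spectra
  for (seed in 1:5) {
    set.seed(seed)
    calls4 <- replicate(14, unique(sample(c("h1", "h2", "h3"), 2, TRUE)),
                        simplify = FALSE)
    gt4 <- toy_gt(calls4, kind = "sequence_diploid", locus = "s",
                  alignments = list(s = aln))
    pm4 <- toy_popmap(gt4, 7)
    ph4 <- phi_st_amova(gt4, pm4, "s", "identity", n_perm = 0)
    cnt <- lapply(c("A", "B"), function(p)
      allele_frequencies(gt4, pm4, "s", p)$counts)
    expect_equal(ph4$phi_st, oracle_hap_fst_from_spectra(cnt),
                 tolerance = 1e-10)
  }
})

test_that("Jost's D_est: limits, oracle, multilocus harmonic mean", {
  eq <- list(c(a = 30, b = 20), c(a = 30, b = 20))
  expect_lt(abs(jost_dest(eq)$D_est), 0.03)

  fixed <- list(c(a = 100), c(b = 100))
  expect_gt(jost_dest(fixed)$D_est, 0.99)

  toy <- list(c(a = 35, b = 15), c(a = 15, b = 35))
  expect_equal(jost_dest(toy)$D_est, oracle_jost_d(toy), tolerance = 1e-12)

  hm <- jost_dest_multilocus(c(0.2, 0.4))
  expect_equal(hm$harmonic_mean, 2 / (1 / 0.2 + 1 / 0.4))
  expect_warning(jost_dest_multilocus(c(0.5, -0.01)), "floored")
})

test_that("F': limits, shared Dice kernel with APD, and D=1/F'=1 case", {
  ids <- c("h1", paste0("x", 1:6))
  aln <- locus_alignment("s", ids,
                         vapply(seq_along(ids), function(i)
                           strrep(c("A", "C", "G", "T")[i %% 4 + 1], 20),
                           ""))
  # every pair of individuals (within or between) shares exactly one
  # allele, so all similarities are 0.5 and F' = 0 exactly
  calls <- lapply(1:6, function(i) c("h1", paste0("x", i)))
  gt <- toy_gt(calls, kind = "sequence_diploid", locus = "s",
               alignments = list(s = aln))
  fp <- f_prime(gt, toy_popmap(gt, 3), "s")
  expect_equal(fp$f_prime, 0, tolerance = 1e-12)

  # panmictic pool split in two: mean F' near 0
  set.seed(43)
  fps <- replicate(60, {
    cl <- replicate(16, unique(sample(ids, 2, TRUE)), simplify = FALSE)
    gtp <- toy_gt(cl, kind = "sequence_diploid", locus = "s",
                  alignments = list(s = aln))
    f_prime(gtp, toy_popmap(gtp, 8), "s")$f_prime
  })
  expect_lt(abs(mean(fps)), 0.03)

  # within-similarity 1, between 0 -> F' = 1, and D_est = 1 on the spectra
  calls2 <- c(rep(list("h1"), 4), rep(list("x1"), 4))
  gt2 <- toy_gt(calls2, kind = "sequence_diploid", locus = "s",
                alignments = list(s = aln))
  pm2 <- toy_popmap(gt2, 4)
  fp2 <- f_prime(gt2, pm2, "s")
  expect_equal(fp2$f_prime, 1)
  cnt <- lapply(c("A", "B"), function(p)
    allele_frequencies(gt2, pm2, "s", p)$counts)
  expect_gt(jost_dest(cnt)$D_est, 0.99)

  # APD relation: 100 * (1 - mean within similarity) reproduces apd()
  set.seed(41)
  calls3 <- replicate(12, unique(sample(c("h1", "x1", "x2", "x3"),
                                        sample(1:2, 1), TRUE)),
                      simplify = FALSE)
  gt3 <- toy_gt(calls3, kind = "sequence_diploid", locus = "s",
                alignments = list(s = aln))
  pm3 <- toy_popmap(gt3, 6)
  fp3 <- f_prime(gt3, pm3, "s")
  apd_a <- apd(gt3, pm3, "s", "A")$APD
  apd_b <- apd(gt3, pm3, "s", "B")$APD
  expect_equal(100 * (1 - fp3$S_within), mean(c(apd_a, apd_b)),
               tolerance = 1e-12)
})

test_that("exact differentiation test agrees with Fisher on 2x2 tables", {
  tab <- matrix(c(12, 3, 5, 10), 2, 2)
  res <- exact_test_differentiation(tab, mc_steps = 100000,
                                    dememorization = 5000, seed = 2)
  expect_lt(abs(res$p - fisher.test(tab)$p.value), 0.01)

  even <- matrix(c(20, 20, 20, 20), 2, 2)
  expect_gt(exact_test_differentiation(even, 20000, 2000, seed = 3)$p, 0.5)

  # disjoint allele sets are decisively rejected
  disj <- matrix(c(15, 15, 0, 0, 0, 0, 15, 15), 4, 2)
  expect_lt(exact_test_differentiation(disj, 50000, 5000, seed = 4)$p,
            0.001)

  expect_warning(p0 <- exact_test_differentiation(matrix(c(5, 0, 7, 0),
                                                         2, 2)),
                 "margin")
  expect_equal(p0$p, 1)
})

test_that("differentiation statistics are centred at 0 under panmixia", {
  set.seed(47)
  stats <- replicate(60, {
    copies <- sample(sprintf("h%d", 1:5), 60, TRUE,
                     prob = c(0.4, 0.25, 0.15, 0.1, 0.1))
    cnt <- lapply(list(copies[1:30], copies[31:60]),
                  function(cc) table(cc))
    c(fst = oracle_hap_fst_from_spectra(cnt),
      d = jost_dest(lapply(cnt, function(x) {
        v <- as.numeric(x); names(v) <- names(x); v
      }))$D_est)
  })
  expect_lt(abs(mean(stats["fst", ])), 0.015)
  expect_lt(abs(mean(stats["d", ])), 0.015)
})
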
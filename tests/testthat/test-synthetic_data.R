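# Generators: seed determinism, closed-form error-model checks, and
# distributional sanity of the coalescent and forward-time engines.

small_scenario <- function(...) {
  sim_scenario(N_e = 80L, n_per_pop = c(12L, 12L), n_msat_loci = 3L,
               m = 0.01, M = 4, ...)
}

test_that("every generator is bit-reproducible under a fixed seed", {
  sc <- small_scenario()
  a <- simulate_msat_two_pop(sc, seed = 1, burnin_factor = 3)
  b <- simulate_msat_two_pop(sc, seed = 1, burnin_factor = 3)
  expect_identical(a, b)

  s1 <- simulate_seq_two_pop(sc, "intron", seed = 2)
  s2 <- simulate_seq_two_pop(sc, "intron", seed = 2)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)

  e1 <- simulate_expansion(sc, n_copies = 20, seed = 3)
  e2 <- simulate_expansion(sc, n_copies = 20, seed = 3)
  f1 <- tempfile(); f2 <- tempfile()
  write_locus_alignment(e1, f1); write_locus_alignment(e2, f2)
  expect_identical(readLines(f1), readLines(f2))

  b1 <- simulate_balancing_locus(sc, seed = 4, generations = 200)
  b2 <- simulate_balancing_locus(sc, seed = 4, generations = 200)
  expect_identical(b1$genotypes$calls, b2$genotypes$calls)
})

test_that("zero mutation rate yields a single allele, S = 0", {
  sc <- small_scenario()
  sc$seq_loci$theta[sc$seq_loci$locus_id == "intron"] <- 0
  r <- simulate_seq_two_pop(sc, "intron", seed = 5)
  expect_length(r$alignment$allele_ids, 1)
  expect_equal(seq_diversity_stats(r$alignment, r$copies)$S, 0)
})

test_that("segregating sites beyond sequence capacity raise an error", {
  sc <- small_scenario()
  sc$seq_loci$length_bp[sc$seq_loci$locus_id == "intron"] <- 4L
  sc$seq_loci$theta[sc$seq_loci$locus_id == "intron"] <- 50
  expect_error(simulate_seq_two_pop(sc, "intron", seed = 6), "capacity")
})

test_that("migration suppresses microsatellite differentiation (island model)", {
  sc_hi <- sim_scenario(N_e = 60L, n_per_pop = c(12L, 12L), n_msat_loci = 4L,
                        m = 0.5)
  sc_no <- sim_scenario(N_e = 60L, n_per_pop = c(12L, 12L), n_msat_loci = 4L,
                        m = 0)
  n_rep <- 12
  worse <- 0; low <- 0
  for (i in seq_len(n_rep)) {
    hi <- simulate_msat_two_pop(sc_hi, seed = 100 + i, burnin_factor = 8)
    no <- simulate_msat_two_pop(sc_no, seed = 100 + i, burnin_factor = 8)
    th_hi <- wc_fst(hi$genotypes, hi$popmap, n_boot = 0, n_perm = 0)$theta
    th_no <- suppressWarnings(
      wc_fst(no$genotypes, no$popmap, n_boot = 0, n_perm = 0)$theta)
    if (th_no > th_hi) worse <- worse + 1
    if (th_hi < 0.05) low <- low + 1
  }
  expect_gte(worse / n_rep, 0.9)   # isolation always increases theta here
  expect_gte(low / n_rep, 0.9)     # strong migration keeps theta near 0
})

test_that("neutral single-deme sequences calibrate Tajima's D near 0", {
  sc <- small_scenario()
  sc$seq_loci$theta[sc$seq_loci$locus_id == "intron"] <- 5
  sc$seq_loci$indel_events[sc$seq_loci$locus_id == "intron"] <- 0L
  set.seed(11)
  sims <- mhccontrast:::sim_neutral_k(30, 600, theta = 5)
  ok <- sims[, "S"] >= 1
  d <- oracle_tajima_d(sims[ok, "S"], sims[ok, "k"], 30)
  expect_lt(abs(mean(d)), 0.15)
})

test_that("multicopy detection dropout thins copy numbers binomially", {
  # fully heterozygous base: every individual has 4 distinct copies
  n <- 200
  calls_a <- lapply(seq_len(n), function(i) c("a1", "a2"))
  calls_b <- lapply(seq_len(n), function(i) c("b1", "b2"))
  base <- genotype_table(sprintf("i%03d", 1:n),
                         data.frame(locus_id = c("A", "B"),
                                    kind = "sequence_diploid"),
                         list(A = calls_a, B = calls_b))
  sc <- small_scenario()
  sc$multicopy_dropout <- 0
  full <- simulate_multicopy_genotypes(sc, base, loci = c("A", "B"),
                                       seed = 1)
  expect_true(all(lengths(full$calls$mhc_multi) == 4L))

  sc$multicopy_dropout <- 1
  none <- simulate_multicopy_genotypes(sc, base, loci = c("A", "B"),
                                       seed = 1)
  expect_true(all(lengths(none$calls$mhc_multi) == 0L))

  sc$multicopy_dropout <- 0.3
  reps <- 40
  pass <- 0
  for (i in seq_len(reps)) {
    th <- simulate_multicopy_genotypes(sc, base, loci = c("A", "B"),
                                       seed = 100 + i)
    obs <- tabulate(lengths(th$calls$mhc_multi) + 1L, nbins = 5L)
    expe <- dbinom(0:4, 4, 0.7) * n
    gof <- sum((obs - expe)^2 / expe)
    if (pchisq(gof, df = 4, lower.tail = FALSE) > 0.01) pass <- pass + 1
  }
  expect_gte(pass / reps, 0.95)
})

test_that("PCR replicate error model matches its closed forms", {
  n <- 2500
  truth <- toy_gt(replicate(n, c("100", "104"), simplify = FALSE))
  clean <- generate_pcr_replicates(truth, list(dropout = 0,
                                               false_allele = 0), 3,
                                   seed = 1)
  expect_true(all(vapply(clean$calls$L1, function(x)
    all(vapply(x, function(g) identical(g, c("100", "104")), TRUE)), TRUE)))

  allhom <- generate_pcr_replicates(truth, list(dropout = 1,
                                                false_allele = 0), 2,
                                    seed = 2)
  expect_true(all(vapply(allhom$calls$L1, function(x)
    all(vapply(x, function(g) length(g) == 0 || g[1] == g[2], TRUE)), TRUE)))

  # dropout 0.2: a het is miscalled (hom or failed) w.p. 1-(1-d)^2 = 0.36
  rc <- generate_pcr_replicates(truth, list(dropout = 0.2,
                                            false_allele = 0), 2, seed = 3)
  mis <- unlist(lapply(rc$calls$L1, function(x)
    vapply(x, function(g) length(g) == 0 || g[1] == g[2], TRUE)))
  expect_lt(abs(mean(mis) - 0.36), 0.02)
})

test_that("balancing locus: null mode matches neutral drift, selection is directional", {
  sc <- small_scenario()
  # s = 0 run is distributionally indistinguishable from the neutral mode
  sc$selection <- list(mode = "overdominant", s = 0)
  scn <- sc; scn$selection <- list(mode = "neutral", s = 0)
  ks_pass <- 0
  reps <- 12
  for (i in seq_len(reps)) {
    a <- simulate_balancing_locus(sc, seed = 50 + i, generations = 300)
    b <- simulate_balancing_locus(scn, seed = 150 + i, generations = 300)
    fa <- sort(table(unlist(a$genotypes$calls$mhc_exon)), decreasing = TRUE)
    fb <- sort(table(unlist(b$genotypes$calls$mhc_exon)), decreasing = TRUE)
    p <- suppressWarnings(ks.test(as.numeric(fa), as.numeric(fb))$p.value)
    if (p > 0.01) ks_pass <- ks_pass + 1
  }
  expect_gte(ks_pass / reps, 0.95)

  # overdominance flattens the spectrum: lower top-allele frequency and
  # lower F_ST than neutral in most paired runs
  sc$selection <- list(mode = "overdominant", s = 0.3)
  dir_ok <- 0; defined <- 0
  for (i in seq_len(reps)) {
    a <- simulate_balancing_locus(sc, seed = 250 + i, generations = 600,
                                  mu = 2e-3)
    b <- simulate_balancing_locus(scn, seed = 350 + i, generations = 600,
                                  mu = 2e-3)
    counts2 <- function(r) lapply(c("pop1", "pop2"), function(p)
      allele_frequencies(r$genotypes, r$popmap, "mhc_exon", p)$counts)
    fst_a <- oracle_hap_fst_from_spectra(counts2(a))
    fst_b <- oracle_hap_fst_from_spectra(counts2(b))
    if (is.finite(fst_a) && is.finite(fst_b)) {
      defined <- defined + 1
      if (fst_a <= fst_b + 1e-12) dir_ok <- dir_ok + 1
    }
  }
  expect_gte(defined, 8)
  expect_gte(dir_ok / defined, 0.75)
})

test_that("skewed mode pins the focal allele near its target", {
  sc <- small_scenario()
  sc$selection <- list(mode = "skewed", s = 0.3, target_freq = 0.44)
  ff <- vapply(1:8, function(i)
    simulate_balancing_locus(sc, seed = 500 + i,
                             generations = 400)$focal_freq[1], 0)
  expect_true(all(abs(ff - 0.44) < 0.05))
})

test_that("expansion generator: equilibrium mean and unimodal mode", {
  sc <- small_scenario()
  sc$expansion <- list(tau = 0, theta0 = 4, theta1 = 4)
  set.seed(21)
  ks <- replicate(150, {
    x <- mhccontrast:::sim_mismatch_histogram(25, 0, 4, 4)
    sum((seq_along(x) - 1) * x)
  })
  expect_lt(abs(mean(ks) - 4), 0.6)   # mean pairwise differences ~ theta0

  sc$expansion <- list(tau = 5, theta0 = 1, theta1 = 1000)
  modes <- vapply(1:40, function(i) {
    aln <- simulate_expansion(sc, n_copies = 50, seed = 600 + i)
    x <- mismatch_histogram(aln)
    which.max(x) - 1
  }, 0)
  expect_gte(mean(modes >= 3 & modes <= 7), 0.8)
})

test_that("negative expansion time is rejected", {
  sc <- small_scenario()
  sc$expansion$tau <- -1
  expect_error(simulate_expansion(sc, n_copies = 10), "tau")
})
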
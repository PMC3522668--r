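# Consensus genotyping, error rates, null-allele EM, exact HWE and LD.

test_that("consensus rules: 2-PCR heterozygote, 3-PCR homozygote, conflicts", {
  expect_equal(consensus_genotype(list(c("A", "B"), c("A", "B"))),
               c("A", "B"))
  expect_equal(consensus_genotype(rep(list(c("A", "A")), 3)), c("A", "A"))
  # two concordant homozygous PCRs are not enough for a homozygote call:
  # the allele is confirmed but the genotype degrades to half-locus
  expect_equal(consensus_genotype(rep(list(c("A", "A")), 2)), c("A", NA))
  # B seen once in 7 PCRs blocks the homozygote -> half-locus call
  calls <- c(list(c("A", "A")), list(c("A", "B")), rep(list(c("A", "A")), 5))
  expect_equal(consensus_genotype(calls), c("A", NA))
  # conflict resolved once the second allele is confirmed
  expect_equal(consensus_genotype(list(c("A", "A"), c("A", "B"),
                                       c("A", "B"))), c("A", "B"))
  # tie-break: two confirmed alleles + a third singleton -> the confirmed pair
  expect_equal(consensus_genotype(list(c("A", "B"), c("A", "C"),
                                       c("B", "B"))), c("A", "B"))
  expect_equal(consensus_genotype(list()), character(0))
  # failed PCRs are skipped, not counted as discordance
  expect_equal(consensus_genotype(list(c("A", "A"), character(0),
                                       c("A", "A"), c("A", "A"))),
               c("A", "A"))
})

test_that("consensus never reports an allele observed once", {
  set.seed(7)
  alleles <- c("a", "b", "c", "d")
  for (rep_i in 1:200) {
    n_pcr <- sample(1:7, 1)
    calls <- replicate(n_pcr, sample(alleles, 2, replace = TRUE),
                       simplify = FALSE)
    out <- consensus_genotype(calls)
    seen <- table(unlist(lapply(calls, unique)))
    for (a in out[!is.na(out)]) expect_gte(seen[[a]], 2)
  }
})

test_that("paired-sample error rates match their definitions", {
  ref <- toy_gt(c(replicate(100, c("1", "2"), simplify = FALSE),
                  replicate(50, c("1", "1"), simplify = FALSE)))
  er0 <- genotyping_error_rates(ref, ref)
  expect_true(all(er0[, c("allelic_dropout", "false_allele",
                          "total_error")] == 0))

  # one het observed as homozygote for a true allele among 100 het refs
  test_calls <- ref$calls$L1
  test_calls[[1]] <- c("1", "1")
  tst <- toy_gt(test_calls)
  er <- genotyping_error_rates(ref, tst)
  row <- er[er$locus == "L1", ]
  expect_equal(row$allelic_dropout, 0.01)
  expect_equal(row$false_allele, 0)
  expect_equal(row$total_error, 1 / (2 * 150))

  # no overlap -> undefined
  miss <- toy_gt(rep(list(character(0)), 150))
  expect_error(genotyping_error_rates(ref, miss), "undefined")
})

test_that("consensus genotyping beats a single PCR on simulated fecal data", {
  set.seed(11)
  n <- 300
  truth <- toy_gt(replicate(n, sample(as.character(c(100, 104, 108)), 2,
                                      replace = TRUE), simplify = FALSE))
  rc <- generate_pcr_replicates(truth, list(dropout = 0.2,
                                            false_allele = 0.01), 5,
                                seed = 12)
  cons <- consensus_genotype_table(rc)
  single <- toy_gt(lapply(rc$calls$L1, function(x)
    if (length(x[[1]]) == 2) x[[1]] else character(0)))
  err_cons <- genotyping_error_rates(truth, cons)
  err_single <- genotyping_error_rates(truth, single)
  expect_lt(err_cons$total_error[err_cons$locus == "overall"],
            err_single$total_error[err_single$locus == "overall"])
})

test_that("null-allele EM: boundary cases and parameter recovery", {
  # counts exactly at HW proportions, no blanks -> NAF ~ 0
  g <- c(rep(list(c("a", "a")), 9), rep(list(c("a", "b")), 12),
         rep(list(c("b", "b")), 4))
  fit <- null_allele_em(g)
  expect_lt(fit$naf, 1e-6)
  expect_true(all(diff(fit$loglik) > -1e-9))   # EM never decreases loglik

  # all blank -> degenerate NAF = 1
  blank <- rep(list(character(0)), 20)
  expect_equal(null_allele_em(blank,
                              include_missing_as_null = TRUE)$naf, 1)

  # recovery of a true null frequency of 0.2 (visible blanks)
  set.seed(13)
  est <- replicate(40, {
    draw <- replicate(500, sample(c("a", "b", "c", "null"), 2, TRUE,
                                  c(0.35, 0.25, 0.2, 0.2)),
                      simplify = FALSE)
    obs <- lapply(draw, function(x) {
      v <- x[x != "null"]
      if (!length(v)) character(0) else if (length(v) == 1) rep(v, 2) else v
    })
    null_allele_em(obs, include_missing_as_null = TRUE)$naf
  })
  expect_lt(abs(mean(est) - 0.2), 0.03)
})

test_that("HWE exact test agrees with exhaustive enumeration on 2 alleles", {
  # n = 10, 2 alleles: enumerate all pairings via the heterozygote count
  g <- c(rep(list(c("a", "a")), 4), rep(list(c("a", "b")), 2),
         rep(list(c("b", "b")), 4))
  counts <- table(unlist(g))
  n <- 10
  lp_all <- c(); pr_all <- c()
  n_het_possible <- seq(counts[["b"]] %% 2, min(counts), by = 2)
  for (h in n_het_possible) {
    naa <- (counts[["a"]] - h) / 2
    nbb <- (counts[["b"]] - h) / 2
    lp <- lfactorial(n) - lfactorial(naa) - lfactorial(nbb) -
      lfactorial(h) + h * log(2) +
      sum(lfactorial(counts)) - lfactorial(2 * n)
    lp_all <- c(lp_all, lp); pr_all <- c(pr_all, exp(lp))
  }
  expect_equal(sum(pr_all), 1, tolerance = 1e-9)
  lp_obs <- lp_all[n_het_possible == 2]
  p_exact <- sum(pr_all[lp_all <= lp_obs + 1e-12])
  res <- hwe_exact_mc(g, n_mc = 30000, seed = 3)
  expect_lt(abs(res$p - p_exact), 0.01)

  # strong heterozygote deficit -> tiny one-sided p
  g2 <- c(rep(list(c("a", "a")), 25), rep(list(c("b", "b")), 25))
  res2 <- hwe_exact_mc(g2, n_mc = 20000, seed = 4)
  expect_lt(res2$p_het_deficiency, 0.001)

  expect_warning(hwe_exact_mc(rep(list(c("a", "a")), 5)), "monomorphic")
})

test_that("LD permutation test: identity, null uniformity, guards", {
  set.seed(21)
  g1 <- replicate(40, sample(c("1", "2", "3"), 2, TRUE), simplify = FALSE)
  res <- ld_permutation_test(g1, g1, n_perm = 200, seed = 1)
  expect_lte(res$p, 1 / 100)

  # independent loci: p roughly uniform
  ps <- replicate(120, {
    a <- replicate(30, sample(c("1", "2"), 2, TRUE), simplify = FALSE)
    b <- replicate(30, sample(c("x", "y"), 2, TRUE), simplify = FALSE)
    ld_permutation_test(a, b, n_perm = 60,
                        seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  expect_error(ld_permutation_test(g1, g1, n_perm = 0), "positive")
  mono <- rep(list(c("1", "1")), 40)
  expect_warning(ld_permutation_test(g1, mono), "categories")
})
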
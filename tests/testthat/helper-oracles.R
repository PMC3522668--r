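# Independent oracle implementations used to cross-check the package code.
# These deliberately re-derive each quantity from first principles (direct
# sums, enumeration) and never call the implementation they verify.

# Tajima's D straight from the textbook constants, coded independently
oracle_tajima_d <- function(S, k, n) {
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# exact unsigned Stirling numbers of the first kind (integer arithmetic)
oracle_stirling1 <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (m in 1:n) for (k in 1:m) {
    s[m + 1, k + 1] <- (m - 1) * s[m, k + 1] + s[m, k]
  }
  s[n + 1, 2:(n + 1)]
}

# all integer partitions of n into exactly K parts (decreasing)
oracle_partitions <- function(n, K, max_part = n) {
  if (K == 1) { if (n <= max_part) return(list(n)) else return(list()) }
  out <- list()
  for (first in min(n - K + 1, max_part):1) {
    for (rest in oracle_partitions(n - first, K - 1, first))
      out[[length(out) + 1]] <- c(first, rest)
  }
  out
}

# Ewens conditional probability of a configuration, via brute normalization
# over all partitions with the same (n, K)
oracle_ewens_conditional <- function(config) {
  config <- sort(config[config > 0], decreasing = TRUE)
  n <- sum(config); K <- length(config)
  weight <- function(cf) {
    a <- table(cf)
    exp(lfactorial(n) - sum(log(cf)) - sum(lfactorial(a)))
  }
  parts <- oracle_partitions(n, K)
  w <- vapply(parts, weight, 0)
  idx <- which(vapply(parts, function(p)
    identical(as.integer(sort(p, decreasing = TRUE)),
              as.integer(config)), TRUE))
  w[idx] / sum(w)
}

# Weir & Cockerham (1984) theta, written as an independent direct
# transcription over alleles (structure differs from the package version)
oracle_wc_theta <- function(geno_by_pop) {
  alleles <- unique(unlist(geno_by_pop))
  r <- length(geno_by_pop)
  n_i <- vapply(geno_by_pop, nrow, 0L)
  nbar <- mean(n_i); nsum <- sum(n_i)
  nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
  num <- den <- 0
  for (al in alleles) {
    p <- vapply(geno_by_pop, function(g) sum(g == al) / (2 * nrow(g)), 0)
    h <- vapply(geno_by_pop, function(g)
      sum(xor(g[, 1] == al, g[, 2] == al)) / nrow(g), 0)
    pbar <- sum(n_i * p) / nsum
    hbar <- sum(n_i * h) / nsum
    s2 <- sum(n_i * (p - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# one-level AMOVA Phi from explicit double-loop sums of squared distances
oracle_amova_phi <- function(copy_ids, labels, d2) {
  N <- length(copy_ids)
  ss <- function(sel) {
    tot <- 0
    idx <- which(sel)
    for (i in idx) for (j in idx) tot <- tot + d2[copy_ids[i], copy_ids[j]]
    tot / (2 * sum(sel))
  }
  ss_tot <- ss(rep(TRUE, N))
  pops <- unique(labels)
  ss_w <- sum(vapply(pops, function(p) ss(labels == p), 0))
  n_p <- vapply(pops, function(p) sum(labels == p), 0)
  df_a <- length(pops) - 1; df_w <- N - length(pops)
  ms_w <- ss_w / df_w
  nprime <- (N - sum(n_p^2) / N) / df_a
  s2a <- ((ss_tot - ss_w) / df_a - ms_w) / nprime
  s2a / (s2a + ms_w)
}

# haplotype-frequency F_ST from spectra only (identity-distance AMOVA in
# closed form: pair counts from haplotype counts)
oracle_hap_fst_from_spectra <- function(counts_by_pop) {
  alleles <- sort(unique(unlist(lapply(counts_by_pop, names))))
  counts_by_pop <- lapply(counts_by_pop, function(cn) {
    v <- setNames(numeric(length(alleles)), alleles)
    v[names(cn)] <- cn
    v
  })
  N_h <- Reduce(`+`, counts_by_pop)
  n_p <- vapply(counts_by_pop, sum, 0)
  N <- sum(n_p)
  ss_tot <- (N^2 - sum(N_h^2)) / (2 * N)
  ss_w <- sum(vapply(counts_by_pop, function(cn)
    (sum(cn)^2 - sum(cn^2)) / (2 * sum(cn)), 0))
  df_a <- length(counts_by_pop) - 1; df_w <- N - length(counts_by_pop)
  ms_w <- ss_w / df_w
  nprime <- (N - sum(n_p^2) / N) / df_a
  s2a <- ((ss_tot - ss_w) / df_a - ms_w) / nprime
  s2a / (s2a + ms_w)
}

# Jost D_est from first principles with the same estimator conventions
oracle_jost_d <- function(counts_by_pop) {
  k <- length(counts_by_pop)
  n_p <- vapply(counts_by_pop, sum, 0)
  alleles <- sort(unique(unlist(lapply(counts_by_pop, names))))
  p <- sapply(counts_by_pop, function(cn) {
    v <- setNames(numeric(length(alleles)), alleles)
    v[names(cn)] <- cn / sum(cn); v
  })
  ntilde <- k / sum(1 / n_p)
  hs <- ntilde / (ntilde - 1) * (1 - mean(colSums(p^2)))
  ht <- 1 - sum(rowMeans(p)^2) + hs / (ntilde * k)
  (k / (k - 1)) * (ht - hs) / (1 - hs)
}

# tiny genotype-table builder (single locus)
toy_gt <- function(calls, kind = "microsatellite", locus = "L1",
                   alignments = NULL) {
  genotype_table(sprintf("ind%03d", seq_along(calls)),
                 data.frame(locus_id = locus, kind = kind),
                 setNames(list(calls), locus), alignments)
}

toy_popmap <- function(gt, n1) {
  setNames(rep(c("A", "B"), c(n1, length(gt$individuals) - n1)),
           gt$individuals)
}
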
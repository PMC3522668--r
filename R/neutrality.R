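# Neutrality tests: Tajima's D (fixed-S coalescent p), Fu's F_S (Ewens /
# Stirling-number tail probability), and the Ewens-Watterson homozygosity
# test with Slatkin-style conditional Monte-Carlo p-values.

logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Log unsigned Stirling numbers of the first kind
#'
#' Row `n` of the triangle, computed entirely in log space with the
#' recurrence `|s(n+1, k)| = n |s(n, k)| + |s(n, k-1)|`.
#'
#' @param n sample size.
#' @return numeric vector `log |s(n, k)|` for k = 1..n.
#' @export
log_stirling1 <- function(n) {
  key <- as.character(n)
  hit <- .stirling_cache[[key]]
  if (!is.null(hit)) return(hit)
  row <- 0          # log |s(1,1)|
  if (n > 1L) for (m in 1:(n - 1L)) {
    prev <- c(-Inf, row, -Inf)   # pad k = 0 and k = m+1
    a <- log(m) + prev[2:(m + 2L)]    # m * |s(m, k)|
    b <- prev[1:(m + 1L)]             # |s(m, k-1)|
    hi <- pmax(a, b)
    row <- ifelse(is.finite(hi),
                  hi + log1p(exp(pmin(a, b) - hi)), -Inf)
  }
  .stirling_cache[[key]] <- row
  row
}
.stirling_cache <- new.env(parent = emptyenv())

# standard Tajima constants for sample size n
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, e1 = e1, e2 = e2)
}

# simulate (S_sim, k_sim) pairs under the neutral coalescent.  fixed_S:
# place exactly S mutations multinomially on branches by length
# (Arlequin-style conditioning); otherwise Poisson with rate theta/2.
sim_neutral_k <- function(n, B, S = NULL, theta = NULL) {
  out <- matrix(0, B, 2L, dimnames = list(NULL, c("S", "k")))
  npairs <- choose(n, 2)
  for (b in seq_len(B)) {
    gen <- coal_genealogy(n, theta = 1, M = 0)
    n_nodes <- 2L * n - 1L
    blen <- numeric(n_nodes)
    nz <- gen$parent > 0L
    blen[nz] <- gen$node_time[gen$parent[nz]] -
      gen$node_time[seq_len(n_nodes)][nz]
    blen[blen < 0] <- 0
    sizes <- lengths(branch_tips(gen))
    w <- sizes * (n - sizes)      # pairs split by a mutation on each branch
    if (!is.null(S)) {
      if (sum(blen) <= 0) { out[b, ] <- c(S, 0); next }
      hits <- rmultinom(1L, S, blen)[, 1L]
    } else {
      hits <- rpois(n_nodes, blen * theta / 2)
    }
    out[b, ] <- c(sum(hits), sum(hits * w) / npairs)
  }
  out
}

#' Tajima's D with a fixed-S coalescent p-value
#'
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard constants
#' in `n`.  The p-value is two-tailed, from neutral coalescent samples of
#' size `n` conditioned on the observed number of segregating sites
#' (mutations placed on branches proportionally to branch length).
#'
#' @param S segregating sites (>= 1).
#' @param k mean pairwise differences.
#' @param n gene copies (>= 4).
#' @param n_sim simulated genealogies for the p-value (0 = statistic only).
#' @param seed integer seed.
#' @return list with `D`, `p` (two-tailed), `p_lower`, `p_upper`.
#' @export
tajimas_d <- function(S, k, n, n_sim = 10000L, seed = 1L) {
  if (n < 4L) stop("Tajima's D requires n >= 4")
  if (S < 1L) return(list(D = NA_real_, p = NA_real_,
                          p_lower = NA_real_, p_upper = NA_real_))
  cst <- tajima_constants(n)
  D <- (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  p <- p_lo <- p_hi <- NA_real_
  if (n_sim > 0L) {
    set.seed(seed)
    sim <- sim_neutral_k(n, n_sim, S = S)
    d_sim <- (sim[, "k"] - S / cst$a1) /
      sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    p_lo <- mean(d_sim <= D + 1e-12)
    p_hi <- mean(d_sim >= D - 1e-12)
    p <- min(1, 2 * min(p_lo, p_hi))
  }
  list(D = D, p = p, p_lower = p_lo, p_upper = p_hi)
}

#' Fu's F_S with a coalescent p-value
#'
#' With `theta` estimated by the mean pairwise difference `k`, the tail
#' probability of observing at least `K` alleles is
#' `S' = sum_{j >= K} |s(n, j)| theta^j / theta^(n)` (rising factorial),
#' computed in log space with unsigned Stirling numbers, and
#' `F_S = ln(S' / (1 - S'))`.  The p-value is the proportion of neutral
#' coalescent simulations (at the estimated theta) with `F_S` at most the
#' observed value (Fu's convention: the rejection region is the lower tail).
#'
#' @param K observed distinct alleles (>= 2).
#' @param k mean pairwise differences (> 0).
#' @param n gene copies.
#' @param n_sim coalescent simulations for the p-value (0 = statistic only).
#' @param seed integer seed.
#' @return list with `F_S`, `S_prime`, `p`.
#' @export
fus_fs <- function(K, k, n, n_sim = 10000L, seed = 1L) {
  if (K < 2L) stop("F_S undefined for K < 2")
  if (k <= 0) stop("F_S undefined for zero mean pairwise difference")
  fs_stat <- function(K, theta, n) {
    if (K < 2L || theta <= 0) return(NA_real_)
    ls <- log_stirling1(n)
    lrise <- sum(log(theta + 0:(n - 1L)))
    terms <- ls + seq_len(n) * log(theta) - lrise
    log_sp <- logsumexp(terms[K:n])
    log_sp <- min(log_sp, 0)
    # log(1 - S') computed from the complementary sum for stability
    log_1msp <- if (K > 1L) logsumexp(terms[1:(K - 1L)]) else -Inf
    log_sp - log_1msp
  }
  fs <- fs_stat(K, k, n)
  p <- NA_real_
  if (n_sim > 0L) {
    set.seed(seed)
    fs_sim <- numeric(n_sim)
    for (b in seq_len(n_sim)) {
      gen <- coal_genealogy(n, theta = k, M = 0)
      carriers <- mutation_carriers(gen)
      key <- rep("", n)
      for (m in seq_along(carriers))
        key[carriers[[m]]] <- paste0(key[carriers[[m]]], m, ".")
      K_sim <- length(unique(key))
      k_sim <- if (length(carriers))
        sum(vapply(carriers, function(t_) length(t_) * (n - length(t_)), 0)) /
          choose(n, 2) else 0
      fs_sim[[b]] <- if (K_sim >= 2L && k_sim > 0)
        fs_stat(K_sim, k_sim, n) else Inf
    }
    p <- mean(fs_sim <= fs + 1e-12)
  }
  list(F_S = fs, S_prime = stats::plogis(fs), p = p)
}

#' Log probability of an allele configuration under the Ewens formula
#'
#' Unconditional: the Ewens sampling formula at `theta`.  Conditional on
#' the observed number of alleles `K` (theta-free):
#' `P = n! / (|s(n, K)| prod(n_i) prod(a_j!))` with `a_j` the number of
#' alleles represented `j` times.
#'
#' @param config integer vector of allele counts (multiplicities).
#' @param theta scaled mutation rate (unconditional version).
#' @param conditional condition on (n, K)?
#' @return log probability.
#' @export
ewens_config_logprob <- function(config, theta = NULL, conditional = TRUE) {
  config <- as.integer(config[config > 0])
  n <- sum(config)
  K <- length(config)
  a_j <- table(config)
  base <- lfactorial(n) - sum(log(config)) - sum(lfactorial(a_j))
  if (conditional) {
    ls <- log_stirling1(n)
    base - ls[[K]]
  } else {
    if (is.null(theta) || theta <= 0) stop("theta required")
    base + K * log(theta) - sum(log(theta + 0:(n - 1L)))
  }
}

# choose a proposal theta whose expected allele number matches K
theta_for_K <- function(n, K) {
  if (K <= 1L) return(1e-8)
  if (K >= n) return(1e8)
  f <- function(th) sum(th / (th + 0:(n - 1L))) - K
  uniroot(f, c(1e-8, 1e8), tol = 1e-8)$root
}

#' Ewens-Watterson-Slatkin homozygosity test
#'
#' Compares the observed allele-frequency homozygosity
#' `F_obs = sum (n_i / n)^2` with its neutral expectation conditional on the
#' sample size and number of alleles.  Conditional configurations are drawn
#' by Chinese-restaurant-process sampling retained when the allele number
#' matches (the conditional law is theta-free, so the proposal theta only
#' affects efficiency).  `P_H` is the lower-tail probability
#' `Pr(F <= F_obs)` (low homozygosity = balancing-selection signal); the
#' upper tail and the Slatkin exact-style `P_E` (probability of
#' configurations no more probable than the observed one) are also
#' returned.
#'
#' @param config integer vector of allele counts.
#' @param n_mc accepted Monte-Carlo configurations.
#' @param seed integer seed.
#' @return list with `F_obs`, `F_exp`, `P_H` (lower tail), `P_H_upper`,
#'   `P_E`, `n`, `K`.
#' @export
ewens_watterson_slatkin <- function(config, n_mc = 100000L, seed = 1L) {
  config <- as.integer(config[config > 0])
  n <- sum(config)
  K <- length(config)
  if (n < 2L) stop("need n >= 2")
  if (K > n) stop("more alleles than gene copies")
  f_obs <- sum((config / n)^2)
  if (K == 1L || K == n) {
    # single possible configuration
    return(list(F_obs = f_obs, F_exp = f_obs, P_H = 1, P_H_upper = 1,
                P_E = 1, n = n, K = K))
  }
  set.seed(seed)
  th <- theta_for_K(n, K)
  i_seq <- 0:(n - 1L)
  p_new <- th / (th + i_seq)
  lp_obs <- ewens_config_logprob(config, conditional = TRUE)
  f_sim <- numeric(n_mc); lp_sim <- numeric(n_mc)
  got <- 0L
  max_tries <- n_mc * 1000L
  tries <- 0L
  while (got < n_mc && tries < max_tries) {
    tries <- tries + 1L
    new_tab <- runif(n) < p_new     # K is fixed by these draws alone
    if (sum(new_tab) != K) next
    sizes <- integer(K)
    kcur <- 0L
    for (i in seq_len(n)) {
      if (new_tab[[i]]) { kcur <- kcur + 1L; sizes[[kcur]] <- 1L }
      else {
        j <- sample.int(kcur, 1L, prob = sizes[seq_len(kcur)])
        sizes[[j]] <- sizes[[j]] + 1L
      }
    }
    got <- got + 1L
    f_sim[[got]] <- sum((sizes / n)^2)
    lp_sim[[got]] <- ewens_config_logprob(sizes, conditional = TRUE)
  }
  if (got < n_mc) stop("conditional sampler failed to reach n_mc draws")
  list(F_obs = f_obs, F_exp = mean(f_sim),
       P_H = mean(f_sim <= f_obs + 1e-12),
       P_H_upper = mean(f_sim >= f_obs - 1e-12),
       P_E = mean(lp_sim <= lp_obs + 1e-9),
       n = n, K = K)
}

#' Per-population, per-locus neutrality test table
#'
#' Runs Tajima's D and Fu's F_S (sequence loci with an alignment) and the
#' Ewens-Watterson-Slatkin test (all loci, on allele counts; the multicopy
#' locus uses the estimated counts from its frequency rule, an approximation
#' flagged in the `mode` column).
#'
#' @param gt [genotype_table()].
#' @param popmap population map.
#' @param n_sim simulations for D and F_S p-values.
#' @param n_mc accepted configurations for the E-W-S test.
#' @param seed integer seed.
#' @return data.frame, one row per (population, locus).
#' @export
neutrality_table <- function(gt, popmap, n_sim = 1000L, n_mc = 2000L,
                             seed = 1L) {
  pops <- unique(popmap[gt$individuals])
  rows <- list()
  ctr <- 0L
  for (li in seq_len(nrow(gt$loci))) {
    locus <- gt$loci$locus_id[[li]]
    kind <- gt$loci$kind[[li]]
    mode <- if (kind == "sequence_multicopy") "multicopy" else "diploid"
    for (p in pops) {
      ctr <- ctr + 1L
      sp <- allele_frequencies(gt, popmap, locus, p, mode)
      D <- fs <- p_d <- p_fs <- NA_real_
      aln <- gt$alignments[[locus]]
      if (!is.null(aln) && kind != "microsatellite") {
        copies <- if (kind == "sequence_diploid")
          gene_copies(gt, locus, gt$individuals[popmap[gt$individuals] == p])
        else rep(names(sp$counts), round(sp$counts))
        if (length(copies) >= 4L) {
          sq <- seq_diversity_stats(aln, copies)
          if (sq$S >= 1L) {
            td <- tajimas_d(sq$S, sq$k, length(copies), n_sim,
                            seed = derive_seed(seed, ctr))
            D <- td$D; p_d <- td$p
          }
          if (length(sp$counts) >= 2L && sq$k > 0) {
            ff <- fus_fs(length(sp$counts), sq$k, length(copies), n_sim,
                         seed = derive_seed(seed, ctr + 1000L))
            fs <- ff$F_S; p_fs <- ff$p
          }
        }
      }
      ew <- ewens_watterson_slatkin(round(sp$counts), n_mc,
                                    seed = derive_seed(seed, ctr + 2000L))
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, locus = locus, mode = mode, n = sp$n,
        K = length(sp$counts), D = D, p_D = p_d, F_S = fs, p_FS = p_fs,
        F_obs = ew$F_obs, F_exp = ew$F_exp, P_H = ew$P_H, P_E = ew$P_E)
    }
  }
  do.call(rbind, rows)
}
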
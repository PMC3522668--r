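# Between-population differentiation: Weir-Cockerham theta, K2P distances,
# AMOVA Phi_ST, Jost's D_est, the similarity-based F' and exact tests of
# allele-frequency differentiation.

# complete diploid genotypes (length-2, no NA) at a locus for given
# individuals; returns a 2-column character matrix or NULL
complete_genotypes <- function(gt, locus, individuals) {
  kind <- gt$loci$kind[gt$loci$locus_id == locus]
  idx <- match(individuals, gt$individuals)
  gl <- lapply(gt$calls[[locus]][idx], function(raw) {
    if (length(raw) == 0L || anyNA(raw)) return(NULL)
    if (kind == "sequence_diploid" && length(raw) == 1L) return(rep(raw, 2L))
    if (length(raw) != 2L) return(NULL)
    raw
  })
  gl <- gl[!vapply(gl, is.null, TRUE)]
  if (!length(gl)) return(NULL)
  do.call(rbind, gl)
}

# Weir & Cockerham (1984) variance components for one locus.
# Returns c(a, b, c) summed over alleles, or NULL if monomorphic/unusable.
wc_components <- function(geno_by_pop) {
  geno_by_pop <- geno_by_pop[!vapply(geno_by_pop, is.null, TRUE)]
  geno_by_pop <- geno_by_pop[vapply(geno_by_pop, nrow, 0L) > 0L]
  r <- length(geno_by_pop)
  if (r < 2L) return(NULL)
  alleles <- unique(unlist(lapply(geno_by_pop, as.vector)))
  if (length(alleles) < 2L) return(NULL)
  n_i <- vapply(geno_by_pop, nrow, 0L)
  n_bar <- mean(n_i)
  n_c <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  comp <- c(a = 0, b = 0, c = 0)
  for (al in alleles) {
    p_i <- vapply(geno_by_pop, function(g) mean(g == al), 0)
    h_i <- vapply(geno_by_pop, function(g)
      mean((g[, 1L] == al) != (g[, 2L] == al)), 0)
    p_bar <- sum(n_i * p_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / sum(n_i)
    a <- n_bar / n_c *
      (s2 - 1 / (n_bar - 1) *
         (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
    b <- n_bar / (n_bar - 1) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    comp <- comp + c(a = a, b = b, c = cc)
  }
  comp
}

#' Weir-Cockerham F_ST (theta) with bootstrap CI and permutation p
#'
#' Per-locus and multilocus theta from the Weir & Cockerham (1984) variance
#' components a (among populations), b (among individuals within
#' populations) and c (within individuals), summed over alleles and loci:
#' `theta = sum(a) / sum(a + b + c)`.  The multilocus confidence interval is
#' a percentile bootstrap over loci; p-values permute individuals among
#' populations.
#'
#' @param gt [genotype_table()] with diploid loci.
#' @param popmap population map (>= 2 populations).
#' @param loci loci to use (default: all diploid loci).
#' @param n_boot bootstrap replicates over loci for the multilocus CI.
#' @param n_perm permutations for p-values (0 = skip).
#' @param seed integer seed.
#' @return list with `per_locus` (data.frame locus, theta, p), `theta`
#'   (multilocus), `p` (multilocus permutation p), `ci` (bootstrap CI),
#'   `excluded` (monomorphic loci).
#' @export
wc_fst <- function(gt, popmap, loci = NULL, n_boot = 10000L, n_perm = 1000L,
                   seed = 1L) {
  check_popmap(gt, popmap)
  if (is.null(loci))
    loci <- gt$loci$locus_id[gt$loci$kind != "sequence_multicopy"]
  pops <- unique(popmap[gt$individuals])
  if (length(pops) < 2L) stop("need at least 2 populations")
  set.seed(seed)
  geno <- function(labels) {
    lapply(loci, function(l)
      lapply(pops, function(p)
        complete_genotypes(gt, l, gt$individuals[labels == p])))
  }
  labels0 <- popmap[gt$individuals]
  g0 <- geno(labels0)
  comps <- lapply(g0, wc_components)
  usable <- !vapply(comps, is.null, TRUE)
  if (any(!usable))
    warning("monomorphic/unusable loci excluded: ",
            paste(loci[!usable], collapse = ", "))
  if (!any(usable)) stop("no polymorphic loci")
  cm <- do.call(rbind, comps[usable])
  theta_loc <- cm[, "a"] / rowSums(cm)
  theta_ml <- sum(cm[, "a"]) / sum(cm)
  perm_p_loc <- rep(NA_real_, sum(usable))
  perm_p_ml <- NA_real_
  if (n_perm > 0L) {
    cnt_loc <- numeric(sum(usable)); cnt_ml <- 0
    for (b in seq_len(n_perm)) {
      gl <- geno(sample(labels0))
      cmp <- lapply(gl[usable], wc_components)
      ok <- !vapply(cmp, is.null, TRUE)
      th <- rep(-Inf, sum(usable))
      cmx <- do.call(rbind, cmp[ok])
      th[ok] <- cmx[, "a"] / rowSums(cmx)
      cnt_loc <- cnt_loc + (th >= theta_loc - 1e-12)
      thm <- if (any(ok)) sum(cmx[, "a"]) / sum(cmx) else -Inf
      cnt_ml <- cnt_ml + (thm >= theta_ml - 1e-12)
    }
    perm_p_loc <- cnt_loc / n_perm
    perm_p_ml <- cnt_ml / n_perm
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L && sum(usable) > 1L) {
    bt <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(nrow(cm), replace = TRUE)
      sum(cm[i, "a"]) / sum(cm[i, ])
    }, 0)
    ci <- quantile(bt, c(0.025, 0.975), names = FALSE)
  }
  list(per_locus = data.frame(locus = loci[usable], theta = theta_loc,
                              p = perm_p_loc),
       theta = theta_ml, p = perm_p_ml, ci = ci, excluded = loci[!usable])
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions over sites where neither
#' sequence has a gap (pairwise deletion).  Saturated pairs (a log argument
#' <= 0) return `Inf`.
#'
#' @param s1,s2 equal-length character strings (IUPAC DNA, `-` gaps).
#' @param analyzed_columns optional column subset to use.
#' @return the K2P distance (substitutions per site).
#' @export
k2p_distance <- function(s1, s2, analyzed_columns = NULL) {
  x <- strsplit(toupper(s1), "")[[1L]]
  y <- strsplit(toupper(s2), "")[[1L]]
  if (length(x) != length(y)) stop("sequences must have equal length")
  if (!is.null(analyzed_columns)) { x <- x[analyzed_columns]; y <- y[analyzed_columns] }
  ok <- x %in% BASES & y %in% BASES
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0L) stop("no comparable sites")
  diff <- x != y
  purine <- c("A", "G")
  is_ts <- diff & (x %in% purine) == (y %in% purine)
  P <- sum(is_ts) / n
  Q <- sum(diff & !is_ts) / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(Inf)
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Pairwise K2P distance matrix for a locus alignment
#' @param aln a [locus_alignment()]; gaps are excluded pairwise.
#' @return symmetric matrix of K2P distances between alleles.
#' @export
k2p_matrix <- function(aln) {
  n <- length(aln$allele_ids)
  d <- matrix(0, n, n, dimnames = list(aln$allele_ids, aln$allele_ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- k2p_distance(aln$seqs[[i]], aln$seqs[[j]])
  d
}

#' AMOVA Phi_ST over two or more populations
#'
#' One-level analysis of molecular variance from squared inter-haplotype
#' distances: with `distance = "K2P"` the K2P distances of the alignment are
#' used as squared distances (the convention of the standard AMOVA
#' implementations); `distance = "identity"` scores haplotype pairs 0/1 and
#' yields the conventional haplotype-frequency F_ST.  Significance permutes
#' individuals (both gene copies together) among populations.
#'
#' @param gt [genotype_table()] with the sequence locus.
#' @param popmap population map.
#' @param locus locus id (must have an attached alignment for K2P).
#' @param distance `"K2P"`, `"identity"`, or a precomputed squared-distance
#'   matrix between alleles.
#' @param n_perm number of permutations (0 = skip).
#' @param seed integer seed.
#' @return list with `phi_st`, `p`, variance components `sigma2_a`,
#'   `sigma2_w`, and the populations used.
#' @export
phi_st_amova <- function(gt, popmap, locus, distance = "K2P",
                         n_perm = 1000L, seed = 1L) {
  pops_all <- unique(popmap[gt$individuals])
  copies_by_ind <- allele_multisets(gt, locus, gt$individuals)
  ok <- lengths(copies_by_ind) == 2L
  inds <- gt$individuals[ok]
  copies_by_ind <- copies_by_ind[ok]
  labels <- popmap[inds]
  keep_pop <- names(which(table(labels) >= 1L))
  # drop populations contributing a single gene copy (none possible here
  # since units are complete diploids, but guard small pops)
  sizes <- table(labels)
  if (any(sizes < 1L)) keep_pop <- names(sizes[sizes >= 1L])
  dmat <- if (is.matrix(distance)) distance
  else if (identical(distance, "K2P")) k2p_matrix(gt$alignments[[locus]])
  else if (identical(distance, "identity")) {
    ids <- unique(unlist(copies_by_ind))
    m <- 1 - diag(length(ids)); dimnames(m) <- list(ids, ids); m
  } else stop("unknown distance")
  if (any(!is.finite(dmat))) {
    warning("saturated K2P distances replaced by the largest finite value")
    dmat[!is.finite(dmat)] <- max(dmat[is.finite(dmat)])
  }
  phi_from_labels <- function(labels) {
    copies <- unlist(copies_by_ind, use.names = FALSE)
    copy_lab <- rep(labels, each = 2L)
    idx <- match(copies, rownames(dmat))
    N <- length(copies)
    d2 <- dmat[idx, idx]
    ss_total <- sum(d2) / (2 * N)
    pops <- unique(labels)
    ss_within <- 0
    n_p <- numeric(length(pops))
    for (q in seq_along(pops)) {
      sel <- copy_lab == pops[[q]]
      n_p[[q]] <- sum(sel)
      ss_within <- ss_within + sum(d2[sel, sel]) / (2 * n_p[[q]])
    }
    ss_among <- ss_total - ss_within
    df_a <- length(pops) - 1L
    df_w <- N - length(pops)
    sigma2_w <- ss_within / df_w
    n_prime <- (N - sum(n_p^2) / N) / df_a
    sigma2_a <- (ss_among / df_a - sigma2_w) / n_prime
    list(phi = sigma2_a / (sigma2_a + sigma2_w),
         sigma2_a = sigma2_a, sigma2_w = sigma2_w)
  }
  ob <- phi_from_labels(labels)
  p <- NA_real_
  if (n_perm > 0L) {
    set.seed(seed)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      ph <- phi_from_labels(sample(labels))$phi
      if (ph >= ob$phi - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / n_perm
  }
  list(phi_st = ob$phi, p = p, sigma2_a = ob$sigma2_a,
       sigma2_w = ob$sigma2_w, populations = pops_all)
}

#' Jost's D_est from per-population allele spectra
#'
#' Nearly unbiased within- and total-heterozygosity estimators in the
#' Nei-Chesser style, with gene copies as the sampling unit:
#' `Hs = (ntilde/(ntilde-1)) (1 - mean_p sum_i p_ip^2)` with `ntilde` the
#' harmonic mean of per-population copy counts, `Ht = 1 - sum_i pbar_i^2 +
#' Hs/(ntilde k)`, and `D_est = (k/(k-1)) (Ht - Hs)/(1 - Hs)` for `k`
#' populations.  The multilocus summary is the harmonic mean of per-locus
#' values (non-positive values floored at 1e-6 inside the harmonic mean
#' only, and flagged).
#'
#' @param spectra list of `allele_spectrum` objects, one per population
#'   (same locus), or a list of named count vectors.
#' @return list with `D_est`, `Hs`, `Ht`.
#' @export
jost_dest <- function(spectra) {
  counts <- lapply(spectra, function(s)
    if (inherits(s, "allele_spectrum")) s$counts else s)
  k <- length(counts)
  if (k < 2L) stop("need at least 2 populations")
  n_p <- vapply(counts, sum, 0)
  if (any(n_p < 2)) stop("need at least 2 gene copies per population")
  alleles <- sort(unique(unlist(lapply(counts, names))))
  pmat <- vapply(counts, function(cn) {
    v <- setNames(numeric(length(alleles)), alleles)
    v[names(cn)] <- cn / sum(cn)
    v
  }, numeric(length(alleles)))
  ntilde <- k / sum(1 / n_p)
  hs_plain <- 1 - mean(colSums(pmat^2))
  hs <- ntilde / (ntilde - 1) * hs_plain
  pbar <- rowMeans(pmat)
  ht <- 1 - sum(pbar^2) + hs / (ntilde * k)
  if (hs >= 1) stop("Hs = 1: D_est undefined")
  d <- (k / (k - 1)) * (ht - hs) / (1 - hs)
  list(D_est = d, Hs = hs, Ht = ht)
}

#' Multilocus harmonic mean of per-locus D_est values
#' @param d_values numeric vector of per-locus D_est.
#' @param floor_eps floor applied to non-positive values inside the harmonic
#'   mean (raw values are unchanged).
#' @return list with `harmonic_mean` and `n_floored`.
#' @export
jost_dest_multilocus <- function(d_values, floor_eps = 1e-6) {
  d_values <- d_values[!is.na(d_values)]
  floored <- d_values <= 0
  if (any(floored))
    warning(sum(floored), " non-positive D_est value(s) floored at ",
            floor_eps, " in the harmonic mean")
  dv <- pmax(d_values, floor_eps)
  list(harmonic_mean = length(dv) / sum(1 / dv), n_floored = sum(floored))
}

#' Similarity-based differentiation F' with SE
#'
#' Shares the Dice similarity kernel of [apd()]: with `Sw` the unweighted
#' mean of the within-population mean pairwise similarities and `Sb` the
#' mean over between-population pairs, `F' = (Sw - Sb) / (1 - Sb)`.  The SE
#' propagates var(Sw) and var(Sb) by the delta method treating pairs as
#' independent; a jackknife-over-individuals SE is reported alongside.
#'
#' @param gt [genotype_table()].
#' @param popmap population map (exactly 2 populations used).
#' @param locus locus id.
#' @return list with `f_prime`, `se_delta`, `se_jackknife`, `S_within`,
#'   `S_between`.
#' @export
f_prime <- function(gt, popmap, locus) {
  pops <- unique(popmap[gt$individuals])
  if (length(pops) != 2L) stop("F' is defined here for exactly 2 populations")
  sets_by_pop <- lapply(pops, function(p) {
    s <- allele_multisets(gt, locus,
                          gt$individuals[popmap[gt$individuals] == p])
    s[lengths(s) > 0L]
  })
  if (any(vapply(sets_by_pop, length, 0L) < 2L))
    stop("need at least 2 scored individuals per population")
  core <- function(sets_by_pop) {
    sims_w <- lapply(sets_by_pop, function(sets) {
      1 - pair_percent_differences(sets) / 100
    })
    sims_b <- as.vector(vapply(sets_by_pop[[1L]], function(x)
      vapply(sets_by_pop[[2L]], function(y) dice_similarity(x, y), 0),
      numeric(length(sets_by_pop[[2L]]))))
    sw <- mean(vapply(sims_w, mean, 0))
    sb <- mean(sims_b)
    if (sb >= 1) stop("between-population similarity is 1: F' undefined")
    list(f = (sw - sb) / (1 - sb), sw = sw, sb = sb,
         var_sw = sum(vapply(sims_w, function(v) var(v) / length(v), 0)) / 4,
         var_sb = var(sims_b) / length(sims_b))
  }
  ob <- core(sets_by_pop)
  se_delta <- sqrt(ob$var_sw / (1 - ob$sb)^2 +
                     (ob$sw - 1)^2 * ob$var_sb / (1 - ob$sb)^4)
  # jackknife over individuals
  fj <- numeric(0)
  for (p in 1:2) for (i in seq_along(sets_by_pop[[p]])) {
    red <- sets_by_pop
    red[[p]] <- red[[p]][-i]
    fj <- c(fj, core(red)$f)
  }
  nj <- length(fj)
  se_jack <- sqrt((nj - 1) / nj * sum((fj - mean(fj))^2))
  list(f_prime = ob$f, se_delta = se_delta, se_jackknife = se_jack,
       S_within = ob$sw, S_between = ob$sb)
}

#' Markov-chain exact test of allele-frequency differentiation
#'
#' Metropolis walk over R x C contingency tables with fixed margins
#' (Raymond-Rousset): the p-value is the stationary probability mass of
#' tables no more probable (multivariate hypergeometric) than the observed
#' one.
#'
#' @param counts allele (rows) x population (columns) count matrix.
#' @param mc_steps Markov chain steps retained.
#' @param dememorization burn-in steps.
#' @param seed integer seed.
#' @return list with `p` and the observed log table probability `log_prob`.
#' @export
exact_test_differentiation <- function(counts, mc_steps = 100000L,
                                       dememorization = 10000L, seed = 1L) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    warning("zero row/column margin: exact test undefined, p = 1")
    return(list(p = 1, log_prob = NA_real_))
  }
  R <- nrow(counts); C <- ncol(counts)
  if (R < 2L || C < 2L) {
    warning("degenerate table: p = 1")
    return(list(p = 1, log_prob = NA_real_))
  }
  lp <- function(tab) {
    sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
      lfactorial(sum(tab)) - sum(lfactorial(tab))
  }
  set.seed(seed)
  cur <- counts
  lp_obs <- lp(counts)
  lp_cur <- lp_obs
  n_le <- 0L
  total <- dememorization + mc_steps
  for (step in seq_len(total)) {
    r2 <- sample.int(R, 2L); c2 <- sample.int(C, 2L)
    d <- if (runif(1L) < 0.5) 1L else -1L
    a <- cur[r2[1L], c2[1L]] + d; b <- cur[r2[2L], c2[2L]] + d
    e <- cur[r2[1L], c2[2L]] - d; f <- cur[r2[2L], c2[1L]] - d
    if (min(a, b, e, f) >= 0L) {
      # hypergeometric probability ratio of the +/-1 move
      log_ratio <-
        lfactorial(cur[r2[1L], c2[1L]]) + lfactorial(cur[r2[2L], c2[2L]]) +
        lfactorial(cur[r2[1L], c2[2L]]) + lfactorial(cur[r2[2L], c2[1L]]) -
        lfactorial(a) - lfactorial(b) - lfactorial(e) - lfactorial(f)
      if (log(runif(1L)) < log_ratio) {
        cur[r2[1L], c2[1L]] <- a; cur[r2[2L], c2[2L]] <- b
        cur[r2[1L], c2[2L]] <- e; cur[r2[2L], c2[1L]] <- f
        lp_cur <- lp_cur + log_ratio
      }
    }
    if (step > dememorization && lp_cur <= lp_obs + 1e-9) n_le <- n_le + 1L
  }
  list(p = n_le / mc_steps, log_prob = lp_obs)
}

#' Combine per-locus exact-test p-values (Fisher's method)
#' @param p_values numeric vector of p-values.
#' @return list with `chisq`, `df`, `p`.
#' @export
fisher_combine <- function(p_values) {
  p_values <- pmax(p_values[!is.na(p_values)], 1e-300)
  x2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chisq = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE))
}
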
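# Replicate-PCR consensus genotyping, paired-sample error rates, null-allele
# EM and exact Hardy-Weinberg / linkage-disequilibrium checks.

#' Consensus genotype from replicate PCR calls
#'
#' Implements the comparative multi-tubes rule: a heterozygote is accepted
#' once its two alleles have each been observed in at least two PCRs; a
#' homozygote is accepted after three fully concordant homozygous PCRs.  On
#' any conflict further replicates are consumed until every reported allele
#' has been seen at least twice; if the calls are exhausted (at most 7 PCRs)
#' the result degrades to a half-locus call (exactly one allele seen >= 2;
#' returned as `c(allele, NA)`) or to missing (`character(0)`).  An allele
#' observed in only one PCR is never reported.
#'
#' @param calls list of per-PCR calls, each a length-2 character vector of
#'   allele labels (`character(0)` = failed PCR); at most 7 entries are used.
#' @return length-2 character vector (heterozygote or `c(a, a)` homozygote),
#'   `c(allele, NA)` half-locus call, or `character(0)`.
#' @export
consensus_genotype <- function(calls) {
  if (length(calls) == 0L) return(character(0))
  calls <- calls[seq_len(min(length(calls), 7L))]
  seen <- character(0)           # distinct alleles per informative PCR
  counts <- integer(0)
  hom_allele <- NULL             # running all-concordant homozygote
  concordant_hom <- TRUE
  n_informative <- 0L
  for (g in calls) {
    g <- g[!is.na(g)]
    if (length(g) == 0L) next
    n_informative <- n_informative + 1L
    uniq <- unique(g)
    for (a in uniq) {
      i <- match(a, seen)
      if (is.na(i)) { seen <- c(seen, a); counts <- c(counts, 1L) }
      else counts[[i]] <- counts[[i]] + 1L
    }
    if (concordant_hom) {
      if (length(uniq) == 1L && (is.null(hom_allele) || uniq == hom_allele))
        hom_allele <- uniq
      else concordant_hom <- FALSE
    }
    confirmed <- seen[counts >= 2L]
    if (length(confirmed) == 2L) return(sort(confirmed))
    if (concordant_hom && n_informative >= 3L)
      return(c(hom_allele, hom_allele))
  }
  confirmed <- seen[counts >= 2L]
  if (length(confirmed) == 1L) return(c(confirmed, NA_character_))
  character(0)
}

#' Apply consensus genotyping to a full replicate-call set
#' @param rc a `replicate_calls` object from [generate_pcr_replicates()].
#' @return a [genotype_table()] of consensus calls.
#' @export
consensus_genotype_table <- function(rc) {
  calls <- lapply(rc$loci$locus_id, function(l)
    lapply(rc$calls[[l]], consensus_genotype))
  genotype_table(rc$individuals, rc$loci, setNames(calls, rc$loci$locus_id))
}

#' Genotyping error rates from paired reference and test genotypes
#'
#' Compares genotype tables of the same individuals typed from two sample
#' sources (e.g. blood reference vs fecal test).  Per locus: allelic dropout
#' is the fraction of reference-heterozygous comparisons observed as a
#' homozygote for one of the two true alleles; the false-allele rate is the
#' fraction of comparisons where the test call carries an allele absent from
#' the reference; total error is the fraction of mismatching allele slots
#' (two slots per genotype).  Comparisons with a missing or half-locus call
#' on either side are skipped.
#'
#' @param reference,test [genotype_table()]s over the same individuals/loci.
#' @return data.frame with one row per locus plus an `overall` row
#'   (aggregated counts): columns `locus`, `n_comparisons`, `n_ref_het`,
#'   `allelic_dropout`, `false_allele`, `total_error`.
#' @export
genotyping_error_rates <- function(reference, test) {
  stopifnot(identical(reference$individuals, test$individuals),
            identical(reference$loci$locus_id, test$loci$locus_id))
  rows <- lapply(reference$loci$locus_id, function(l) {
    nc <- 0L; nh <- 0L; drop <- 0L; fa <- 0L; mis <- 0L
    for (i in seq_along(reference$individuals)) {
      r <- reference$calls[[l]][[i]]; t_ <- test$calls[[l]][[i]]
      if (length(r) != 2L || length(t_) != 2L || anyNA(r) || anyNA(t_)) next
      nc <- nc + 1L
      if (r[[1L]] != r[[2L]]) {
        nh <- nh + 1L
        if (t_[[1L]] == t_[[2L]] && t_[[1L]] %in% r) drop <- drop + 1L
      }
      if (length(setdiff(t_, r))) fa <- fa + 1L
      # multiset slot mismatch
      rr <- sort(r); tt <- sort(t_)
      shared <- 0L
      pool <- rr
      for (a in tt) { j <- match(a, pool); if (!is.na(j)) { shared <- shared + 1L; pool <- pool[-j] } }
      mis <- mis + (2L - shared)
    }
    data.frame(locus = l, n_comparisons = nc, n_ref_het = nh,
               allelic_dropout = if (nh > 0L) drop / nh else NA_real_,
               false_allele = if (nc > 0L) fa / nc else NA_real_,
               total_error = if (nc > 0L) mis / (2 * nc) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  if (sum(tab$n_comparisons) == 0L)
    stop("no overlapping genotype comparisons; error rates undefined")
  tot_drop <- sum(tab$allelic_dropout * tab$n_ref_het, na.rm = TRUE)
  tot_fa <- sum(tab$false_allele * tab$n_comparisons, na.rm = TRUE)
  tot_mis <- sum(tab$total_error * 2 * tab$n_comparisons, na.rm = TRUE)
  overall <- data.frame(locus = "overall",
                        n_comparisons = sum(tab$n_comparisons),
                        n_ref_het = sum(tab$n_ref_het),
                        allelic_dropout = if (sum(tab$n_ref_het) > 0L)
                          tot_drop / sum(tab$n_ref_het) else NA_real_,
                        false_allele = tot_fa / sum(tab$n_comparisons),
                        total_error = tot_mis / (2 * sum(tab$n_comparisons)))
  rbind(tab, overall)
}

#' Null-allele frequency by expectation-maximization
#'
#' EM in the style of the FreeNA estimator: apparent homozygotes i/i are
#' apportioned between true i/i and i/null genotypes according to current
#' frequencies, blank genotypes are treated as null/null homozygotes when
#' `include_missing_as_null` is set (otherwise excluded), and frequencies are
#' re-estimated until the largest change falls below `tol`.  Hardy-Weinberg
#' proportions within the population are assumed.
#'
#' @param genotypes list of length-2 allele vectors; `character(0)` entries
#'   are blanks.
#' @param include_missing_as_null treat blanks as null homozygotes.
#' @param tol convergence tolerance on allele frequencies.
#' @param max_iter iteration cap (error on non-convergence).
#' @param n_boot bootstrap pseudoreplicates over individuals (0 = none).
#' @return list with `naf` (null-allele frequency), `freqs` (visible allele
#'   frequencies), `loglik` trace, `iterations`, `boot` (bootstrap NAF draws,
#'   if requested).
#' @export
null_allele_em <- function(genotypes, include_missing_as_null = FALSE,
                           tol = 1e-8, max_iter = 10000L, n_boot = 0L) {
  lens <- lengths(genotypes)
  blanks <- sum(lens == 0L)
  obs <- genotypes[lens == 2L & !vapply(genotypes, anyNA, TRUE)]
  if (!include_missing_as_null) blanks <- 0L
  alleles <- sort(unique(unlist(obs)))
  if (length(alleles) < 2L && blanks == 0L)
    stop("need at least 2 visible alleles")
  if (length(obs) == 0L) {
    if (blanks > 0L)
      return(list(naf = 1, freqs = numeric(0), loglik = numeric(0),
                  iterations = 0L, degenerate = TRUE))
    stop("no usable genotypes")
  }
  K <- length(alleles)
  # observed genotype counts
  hom <- setNames(numeric(K), alleles)
  het <- matrix(0, K, K, dimnames = list(alleles, alleles))
  for (g in obs) {
    i <- match(g[[1L]], alleles); j <- match(g[[2L]], alleles)
    if (i == j) hom[[i]] <- hom[[i]] + 1 else {
      a <- min(i, j); b <- max(i, j); het[a, b] <- het[a, b] + 1
    }
  }
  n_ind <- length(obs) + blanks
  p <- rep(1 / (K + 1), K + 1)   # visible alleles + null
  ll <- numeric(0)
  run_em <- function(hom, het, blanks, n_ind) {
    p <- rep(1 / (K + 1), K + 1)
    ll <- numeric(0)
    for (it in seq_len(max_iter)) {
      r <- p[[K + 1L]]
      # E-step: expected true genotype composition of apparent homozygotes
      exp_in <- hom * (p[seq_len(K)]^2 /
                         (p[seq_len(K)]^2 + 2 * p[seq_len(K)] * r))
      exp_in[is.nan(exp_in)] <- hom[is.nan(exp_in)]
      exp_inull <- hom - exp_in
      cnt <- 2 * exp_in + exp_inull +
        rowSums(het + t(het))[seq_len(K)]
      cnt_null <- sum(exp_inull) + 2 * blanks
      p_new <- c(cnt, cnt_null) / (2 * n_ind)
      # log-likelihood of the observed (collapsed) data
      pv <- p_new[seq_len(K)]; rv <- p_new[[K + 1L]]
      l_ <- sum(hom * log(pmax(pv^2 + 2 * pv * rv, 1e-300))) +
        sum(het[het > 0] * log(pmax(2 * outer(pv, pv), 1e-300)[het > 0])) +
        blanks * log(pmax(rv^2, 1e-300))
      ll <- c(ll, l_)
      delta <- max(abs(p_new - p))
      p <- p_new
      if (delta < tol) return(list(p = p, ll = ll, it = it))
    }
    stop("null-allele EM failed to converge in ", max_iter, " iterations")
  }
  fit <- run_em(hom, het, blanks, n_ind)
  out <- list(naf = fit$p[[K + 1L]],
              freqs = setNames(fit$p[seq_len(K)], alleles),
              loglik = fit$ll, iterations = fit$it)
  if (blanks == 0L) {
    # EM approaches the r = 0 boundary only sublinearly; if the boundary
    # model (plain HW with observed frequencies) is at least as likely as
    # the converged interior point, the MLE is r = 0
    p0 <- (2 * hom + rowSums(het + t(het))[seq_len(K)]) / (2 * n_ind)
    ll0 <- sum(hom * log(pmax(p0^2, 1e-300))) +
      sum(het[het > 0] * log(pmax(2 * outer(p0, p0), 1e-300)[het > 0]))
    if (ll0 >= tail(fit$ll, 1L) - 1e-9) {
      out$naf <- 0
      out$freqs <- setNames(p0, alleles)
    }
  }
  if (n_boot > 0L) {
    keep <- genotypes[lens == 0L | (lens == 2L & !vapply(genotypes, anyNA, TRUE))]
    out$boot <- vapply(seq_len(n_boot), function(b) {
      gs <- keep[sample.int(length(keep), replace = TRUE)]
      res <- tryCatch(null_allele_em(gs, include_missing_as_null,
                                     tol, max_iter, 0L),
                      error = function(e) list(naf = NA_real_))
      res$naf
    }, 0)
  }
  out
}

# log conditional probability of a genotype array given its allele counts
# (Levene's exact distribution)
log_genotype_array_prob <- function(hom, het_count, allele_counts, n) {
  lfactorial(n) - sum(lfactorial(c(hom, het_count))) +
    sum(het_count) * log(2) + sum(lfactorial(allele_counts)) -
    lfactorial(2 * n)
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Shuffles the 2n gene copies into random pairings and compares the
#' conditional (Levene) probabilities of the resulting genotype arrays with
#' the observed one: the two-sided p is the proportion of shuffled arrays at
#' most as probable as observed; the one-sided (heterozygote-deficiency) p
#' orders arrays by their heterozygote count instead.
#'
#' @param genotypes list of length-2 allele vectors (missing/half-locus
#'   entries are skipped).
#' @param n_mc number of Monte-Carlo shuffles.
#' @param seed integer seed.
#' @return list with `p` (two-sided exact-style p), `p_het_deficiency`, `n`,
#'   and `monomorphic` flag.
#' @export
hwe_exact_mc <- function(genotypes, n_mc = 10000L, seed = 1L) {
  obs <- genotypes[lengths(genotypes) == 2L &
                     !vapply(genotypes, anyNA, TRUE)]
  n <- length(obs)
  if (n < 1L) stop("no complete genotypes")
  copies <- unlist(obs)
  alleles <- sort(unique(copies))
  if (length(alleles) < 2L) {
    warning("monomorphic locus: HWE test undefined, p = 1")
    return(list(p = 1, p_het_deficiency = 1, n = n, monomorphic = TRUE))
  }
  set.seed(seed)
  array_stats <- function(a1, a2) {
    ishet <- a1 != a2
    hom_counts <- table(a1[!ishet])
    het_n <- sum(ishet)
    list(lp = log_genotype_array_prob(as.numeric(hom_counts),
                                      rep(1, het_n),
                                      as.numeric(table(c(a1, a2))), n),
         het = het_n)
  }
  g1 <- vapply(obs, `[[`, "", 1L)
  g2 <- vapply(obs, `[[`, "", 2L)
  ob <- array_stats(g1, g2)
  lp_sim <- numeric(n_mc); het_sim <- integer(n_mc)
  for (b in seq_len(n_mc)) {
    perm <- sample(copies)
    st <- array_stats(perm[seq_len(n)], perm[n + seq_len(n)])
    lp_sim[[b]] <- st$lp; het_sim[[b]] <- st$het
  }
  list(p = mean(lp_sim <= ob$lp + 1e-12),
       p_het_deficiency = mean(het_sim <= ob$het),
       n = n, monomorphic = FALSE)
}

#' Permutation test of genotypic linkage disequilibrium between two loci
#'
#' The statistic is the log-likelihood G of the two-locus genotypic
#' contingency table; the null distribution is built by permuting one
#' locus's genotypes across individuals.
#'
#' @param g1,g2 lists of genotype calls (length-2 allele vectors) for the
#'   same individuals.
#' @param n_perm number of permutations (must be positive).
#' @param seed integer seed.
#' @return list with `G`, `p`, `n`.
#' @export
ld_permutation_test <- function(g1, g2, n_perm = 10000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be positive")
  ok <- lengths(g1) == 2L & lengths(g2) == 2L &
    !vapply(g1, anyNA, TRUE) & !vapply(g2, anyNA, TRUE)
  c1 <- vapply(g1[ok], function(g) paste(sort(g), collapse = "/"), "")
  c2 <- vapply(g2[ok], function(g) paste(sort(g), collapse = "/"), "")
  n <- length(c1)
  if (length(unique(c1)) < 2L || length(unique(c2)) < 2L) {
    warning("fewer than 2 genotype categories at a locus; p = 1")
    return(list(G = 0, p = 1, n = n))
  }
  g_stat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    2 * sum(tab[tab > 0] * log(tab[tab > 0] / e[tab > 0]))
  }
  set.seed(seed)
  g_obs <- g_stat(c1, c2)
  g_perm <- vapply(seq_len(n_perm), function(b) g_stat(c1, sample(c2)), 0)
  list(G = g_obs, p = mean(g_perm >= g_obs - 1e-12), n = n)
}
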
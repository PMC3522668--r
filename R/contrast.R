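# Group-comparison statistics, multiple-testing control, and the
# orchestrated two-population contrast.

#' Kruskal-Wallis test with randomization p-value
#'
#' H statistic with tie correction (via [stats::kruskal.test()]); the
#' randomization p is the proportion of label rearrangements with H at
#' least as large as observed.  With two groups and a small arrangement
#' count the enumeration is exhaustive (and labeled so); otherwise `n_perm`
#' random permutations are used.  The asymptotic chi-square p is reported
#' alongside.
#'
#' @param values numeric vector.
#' @param labels group labels (>= 2 groups, >= 2 values each).
#' @param n_perm random permutations.
#' @param exact_limit enumerate exhaustively when the number of two-group
#'   arrangements is at most this.
#' @param seed integer seed.
#' @return data.frame row: statistic, value, df, p, p_asymptotic, method.
#' @export
kruskal_wallis_randomization <- function(values, labels, n_perm = 10000L,
                                         exact_limit = 20000L, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L || any(table(labels) < 2L))
    stop("need >= 2 groups with >= 2 values each")
  h_of <- function(lab) {
    suppressWarnings(unname(kruskal.test(values, lab)$statistic))
  }
  kt <- suppressWarnings(kruskal.test(values, labels))
  h_obs <- unname(kt$statistic)
  if (!is.finite(h_obs)) h_obs <- 0   # all values identical
  n <- length(values)
  method <- "randomization"
  if (nlevels(labels) == 2L &&
      choose(n, sum(labels == levels(labels)[[1L]])) <= exact_limit) {
    idx <- combn(n, sum(labels == levels(labels)[[1L]]))
    hs <- apply(idx, 2L, function(i) {
      lab <- factor(ifelse(seq_len(n) %in% i, levels(labels)[[1L]],
                           levels(labels)[[2L]]))
      h <- h_of(lab)
      if (is.finite(h)) h else 0
    })
    p <- mean(hs >= h_obs - 1e-12)
    method <- "exact_enumeration"
  } else {
    set.seed(seed)
    hs <- vapply(seq_len(n_perm), function(b) {
      h <- h_of(sample(labels))
      if (is.finite(h)) h else 0
    }, 0)
    p <- mean(hs >= h_obs - 1e-12)
  }
  data.frame(statistic = "KW_H", value = h_obs,
             df = nlevels(labels) - 1L, p = p,
             p_asymptotic = if (is.finite(kt$statistic)) kt$p.value else 1,
             method = method)
}

#' Levene's test on absolute residuals from group means
#'
#' One-way ANOVA F on `|value - group mean|`.  Zero within-group residual
#' variance with non-zero between-group spread is flagged as an infinite F.
#'
#' @param values numeric vector.
#' @param labels group labels.
#' @return data.frame row: statistic, value, df1, df2, p, method.
#' @export
levene_test <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L || any(table(labels) < 2L))
    stop("need >= 2 groups with >= 2 values each")
  resid <- abs(values - ave(values, labels))
  aov_tab <- suppressWarnings(anova(lm(resid ~ labels)))
  ms_between <- aov_tab$`Mean Sq`[[1L]]
  ms_within <- aov_tab$`Mean Sq`[[2L]]
  if (ms_within <= 1e-12 * max(ms_between, 1)) {
    f <- if (ms_between <= 1e-300) 0 else Inf
    p <- if (is.infinite(f)) 0 else 1
  } else {
    f <- aov_tab$`F value`[[1L]]
    p <- aov_tab$`Pr(>F)`[[1L]]
  }
  data.frame(statistic = "Levene_W", value = f,
             df1 = aov_tab$Df[[1L]], df2 = aov_tab$Df[[2L]], p = p,
             method = "asymptotic")
}

#' Wilcoxon rank-sum Z test (two groups)
#'
#' Normal-approximation Z from the rank sum with tie and continuity
#' corrections; when both groups have at most 10 observations the
#' two-sided p comes from exhaustive enumeration of rank-sum arrangements
#' instead.
#'
#' @param values numeric vector.
#' @param labels two-group labels.
#' @return data.frame row: statistic, value (Z), W, p, method.
#' @export
wilcoxon_ranksum_z <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly 2 groups required")
  n1 <- sum(labels == levels(labels)[[1L]])
  n2 <- sum(labels == levels(labels)[[2L]])
  if (n1 == 0L || n2 == 0L) stop("empty group")
  n <- n1 + n2
  r <- rank(values)
  w <- sum(r[labels == levels(labels)[[1L]]])
  e_w <- n1 * (n + 1) / 2
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v_w <- n1 * n2 / 12 * ((n + 1) - tie_term)
  cc <- if (w == e_w) 0 else 0.5 * sign(w - e_w)
  z <- if (v_w <= 0) 0 else (w - e_w - cc) / sqrt(v_w)
  if (n1 <= 10L && n2 <= 10L) {
    idx <- combn(n, n1)
    ws <- apply(idx, 2L, function(i) sum(r[i]))
    p <- mean(abs(ws - e_w) >= abs(w - e_w) - 1e-12)
    method <- "exact_enumeration"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "asymptotic"
  }
  data.frame(statistic = "Wilcoxon_Z", value = z, W = w, p = min(p, 1),
             method = method)
}

#' Pearson chi-square test of a contingency table
#'
#' Zero rows/columns are dropped with a warning; a Monte-Carlo p is
#' available for sparse tables.
#'
#' @param counts count matrix.
#' @param monte_carlo use a simulated p-value.
#' @param n_mc Monte-Carlo replicates.
#' @return data.frame row: statistic, value, df, p, method.
#' @export
chisq_contingency <- function(counts, monte_carlo = FALSE, n_mc = 10000L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("zero row/column(s) dropped")
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need >= 2 rows and columns after dropping zeros")
  ct <- suppressWarnings(
    chisq.test(counts, correct = FALSE, simulate.p.value = monte_carlo,
               B = n_mc))
  data.frame(statistic = "ChiSq", value = unname(ct$statistic),
             df = if (monte_carlo) NA_integer_ else unname(ct$parameter),
             p = ct$p.value,
             method = if (monte_carlo) "monte_carlo" else "asymptotic")
}

#' Holm sequential-Bonferroni correction
#'
#' @param p numeric vector of p-values.
#' @param alpha family-wise error rate.
#' @return data.frame: p, p_adjusted (monotone Holm step-down), reject.
#' @export
holm_correction <- function(p, alpha = 0.05) {
  adj <- p.adjust(p, method = "holm")
  data.frame(p = p, p_adjusted = adj, reject = adj <= alpha)
}

#' Run the full two-population contrast
#'
#' Orchestrates diversity, APD (with Kruskal-Wallis and Wilcoxon group
#' comparisons of the pair-level percent differences across populations),
#' differentiation (Weir-Cockerham F_ST for microsatellites with a
#' bootstrap CI; identity-distance F_ST, K2P Phi_ST, the exact test, F' and
#' D_est per sequence locus), neutrality tests, the mismatch analysis of a
#' designated neutral sequence locus, and allele-frequency contingency
#' comparisons, then applies a Holm correction per test family and writes
#' all report tables as TSVs.  Every stage seed derives from the master
#' seed by a fixed counter scheme, so stages are independently
#' reproducible; a stage failure is logged and the remaining stages are
#' attempted.
#'
#' @param dataset list with `genotypes` (a [genotype_table()] carrying any
#'   alignments) and `popmap`.
#' @param out_dir where report TSVs are written (NULL = no files).
#' @param mismatch_locus sequence locus for the mismatch stage (NULL =
#'   first diploid sequence locus).
#' @param n_perm permutations for F_ST / Phi_ST / APD comparisons.
#' @param n_boot bootstrap replicates (F_ST CI, mismatch).
#' @param n_sim coalescent simulations for neutrality p-values.
#' @param n_mc accepted configurations for the E-W-S test, and Markov-chain
#'   steps for the exact differentiation test.
#' @param seed master seed.
#' @return list of result tables (`diversity`, `apd`, `apd_comparisons`,
#'   `differentiation`, `neutrality`, `mismatch`, `frequency_contingency`,
#'   `log`).
#' @export
run_contrast <- function(dataset, out_dir = NULL, mismatch_locus = NULL,
                         n_perm = 1000L, n_boot = 1000L, n_sim = 1000L,
                         n_mc = 5000L, seed = 1L) {
  gt <- dataset$genotypes
  popmap <- dataset$popmap
  if (is.null(gt) || length(gt$individuals) == 0L ||
      nrow(gt$loci) == 0L)
    stop("empty dataset: genotypes with >= 1 locus required")
  check_popmap(gt, popmap, n_pops_exact = 2L)
  pops <- unique(popmap[gt$individuals])
  log_lines <- c(sprintf("master_seed\t%d", seed))
  res <- list()
  try_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      warning("stage ", name, " failed: ", conditionMessage(e))
      NULL
    })
    log_lines <<- c(log_lines, sprintf("stage\t%s\t%s", name,
                                       if (is.null(out)) "failed" else "ok"))
    out
  }

  res$diversity <- try_stage("diversity", diversity_table(gt, popmap))

  res$apd <- try_stage("apd", {
    rows <- list()
    for (locus in gt$loci$locus_id[gt$loci$kind != "microsatellite"])
      for (p in pops)
        rows[[length(rows) + 1L]] <- apd(gt, popmap, locus, p)
    do.call(rbind, rows)
  })

  res$apd_comparisons <- try_stage("apd_comparisons", {
    rows <- list()
    for (locus in gt$loci$locus_id[gt$loci$kind != "microsatellite"]) {
      vals <- list()
      for (p in pops) {
        inds <- gt$individuals[popmap[gt$individuals] == p]
        sets <- allele_multisets(gt, locus, inds)
        sets <- sets[lengths(sets) > 0L]
        vals[[p]] <- pair_percent_differences(sets)
      }
      v <- unlist(vals); lab <- rep(pops, lengths(vals))
      kw <- kruskal_wallis_randomization(v, lab, n_perm = n_perm,
                                         seed = derive_seed(seed, 101L))
      wz <- wilcoxon_ranksum_z(v, lab)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus, KW_H = kw$value, KW_p = kw$p, KW_method = kw$method,
        Z = wz$value, Z_p = wz$p)
    }
    do.call(rbind, rows)
  })

  res$differentiation <- try_stage("differentiation", {
    rows <- list()
    msat <- gt$loci$locus_id[gt$loci$kind == "microsatellite"]
    if (length(msat)) {
      fst <- wc_fst(gt, popmap, msat, n_boot = n_boot, n_perm = n_perm,
                    seed = derive_seed(seed, 201L))
      ps <- vapply(msat, function(l) {
        spectra <- lapply(pops, function(p)
          allele_frequencies(gt, popmap, l, p))
        alleles <- sort(unique(unlist(lapply(spectra, function(s)
          names(s$counts)))))
        cnt <- vapply(spectra, function(s) {
          v <- setNames(numeric(length(alleles)), alleles)
          v[names(s$counts)] <- s$counts
          v
        }, numeric(length(alleles)))
        exact_test_differentiation(round(cnt), mc_steps = n_mc,
                                   dememorization = max(n_mc %/% 10L, 100L),
                                   seed = derive_seed(seed, 202L))$p
      }, 0)
      dvals <- vapply(msat, function(l) {
        spectra <- lapply(pops, function(p)
          allele_frequencies(gt, popmap, l, p))
        tryCatch(jost_dest(spectra)$D_est, error = function(e) NA_real_)
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = "msat_multilocus", F_ST = fst$theta, F_ST_p = fst$p,
        F_ST_ci_lo = fst$ci[[1L]], F_ST_ci_hi = fst$ci[[2L]],
        Phi_ST = NA_real_, Phi_ST_p = NA_real_,
        exact_p = fisher_combine(ps)$p,
        F_prime = NA_real_, F_prime_se = NA_real_,
        D_est = jost_dest_multilocus(dvals)$harmonic_mean)
    }
    for (locus in gt$loci$locus_id[gt$loci$kind != "microsatellite"]) {
      kind <- gt$loci$kind[gt$loci$locus_id == locus]
      mode <- if (kind == "sequence_multicopy") "multicopy" else "diploid"
      spectra <- lapply(pops, function(p)
        allele_frequencies(gt, popmap, locus, p, mode))
      alleles <- sort(unique(unlist(lapply(spectra, function(s)
        names(s$counts)))))
      cnt <- vapply(spectra, function(s) {
        v <- setNames(numeric(length(alleles)), alleles)
        v[names(s$counts)] <- s$counts
        v
      }, numeric(length(alleles)))
      has_aln <- !is.null(gt$alignments[[locus]])
      fst_id <- if (kind == "sequence_diploid")
        phi_st_amova(gt, popmap, locus, "identity", n_perm = n_perm,
                     seed = derive_seed(seed, 203L))
      else list(phi_st = NA_real_, p = NA_real_)
      phi <- if (has_aln && kind == "sequence_diploid")
        phi_st_amova(gt, popmap, locus, "K2P", n_perm = n_perm,
                     seed = derive_seed(seed, 204L))
      else list(phi_st = NA_real_, p = NA_real_)
      fp <- tryCatch(f_prime(gt, popmap, locus),
                     error = function(e) list(f_prime = NA_real_,
                                              se_delta = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus, F_ST = fst_id$phi_st, F_ST_p = fst_id$p,
        F_ST_ci_lo = NA_real_, F_ST_ci_hi = NA_real_,
        Phi_ST = phi$phi_st, Phi_ST_p = phi$p,
        exact_p = exact_test_differentiation(
          round(cnt), mc_steps = n_mc,
          dememorization = max(n_mc %/% 10L, 100L),
          seed = derive_seed(seed, 205L))$p,
        F_prime = fp$f_prime, F_prime_se = fp$se_delta,
        D_est = tryCatch(jost_dest(spectra)$D_est,
                         error = function(e) NA_real_))
    }
    do.call(rbind, rows)
  })

  res$neutrality <- try_stage("neutrality",
    neutrality_table(gt, popmap, n_sim = n_sim, n_mc = n_mc,
                     seed = derive_seed(seed, 301L)))

  res$mismatch <- try_stage("mismatch", {
    if (is.null(mismatch_locus)) {
      cand <- gt$loci$locus_id[gt$loci$kind == "sequence_diploid" &
                                 gt$loci$locus_id %in% names(gt$alignments)]
      mismatch_locus <- if (length(cand)) cand[[1L]] else NULL
    }
    if (is.null(mismatch_locus)) NULL else {
      rows <- list()
      for (p in pops) {
        inds <- gt$individuals[popmap[gt$individuals] == p]
        copies <- gene_copies(gt, mismatch_locus, inds)
        x <- mismatch_histogram(gt$alignments[[mismatch_locus]], copies)
        fit <- fit_sudden_expansion(x)
        bt <- mismatch_bootstrap(x, length(copies), fit, n_boot = n_boot,
                                 seed = derive_seed(seed, 401L))
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, locus = mismatch_locus, tau = fit$tau,
          theta0 = fit$theta0, theta1 = fit$theta1, SSD = fit$SSD,
          p_SSD = bt$p_SSD, raggedness = bt$r_obs,
          p_raggedness = bt$p_raggedness)
      }
      do.call(rbind, rows)
    }
  })

  res$frequency_contingency <- try_stage("frequency_contingency", {
    rows <- list()
    for (locus in gt$loci$locus_id[gt$loci$kind != "microsatellite"]) {
      kind <- gt$loci$kind[gt$loci$locus_id == locus]
      mode <- if (kind == "sequence_multicopy") "multicopy" else "diploid"
      spectra <- lapply(pops, function(p)
        allele_frequencies(gt, popmap, locus, p, mode))
      alleles <- sort(unique(unlist(lapply(spectra, function(s)
        names(s$counts)))))
      cnt <- vapply(spectra, function(s) {
        v <- setNames(numeric(length(alleles)), alleles)
        v[names(s$counts)] <- s$counts
        v
      }, numeric(length(alleles)))
      cs <- tryCatch(chisq_contingency(round(cnt)),
                     error = function(e) NULL)
      if (!is.null(cs))
        rows[[length(rows) + 1L]] <- cbind(data.frame(locus = locus), cs)
    }
    do.call(rbind, rows)
  })

  # Holm correction within each family of locus-level comparisons
  if (!is.null(res$apd_comparisons)) {
    hc <- holm_correction(res$apd_comparisons$KW_p)
    res$apd_comparisons$KW_p_holm <- hc$p_adjusted
  }
  if (!is.null(res$frequency_contingency) &&
      nrow(res$frequency_contingency)) {
    hc <- holm_correction(res$frequency_contingency$p)
    res$frequency_contingency$p_holm <- hc$p_adjusted
  }

  res$log <- log_lines
  if (!is.null(out_dir)) {
    tabs <- res[!vapply(res, is.null, TRUE)]
    tabs$log <- NULL
    write_summary_tables(tabs, out_dir)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  res
}
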
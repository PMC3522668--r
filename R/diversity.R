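# Within-population diversity: allele frequency spectra (diploid and
# multicopy counting rules), rarefied allelic richness, heterozygosity,
# sequence diversity and the average percent difference (APD).

#' Allele frequency spectrum for one locus in one population
#'
#' Diploid mode counts two copies per homozygote and one per allele of a
#' heterozygote (a half-locus call contributes its single scored allele and
#' one fewer gene copy).  Multicopy mode applies the uncertain-copy-number
#' rule: an individual showing a single allele contributes two counts of it,
#' an individual with two or more distinct alleles contributes one count per
#' allele.
#'
#' @param gt a [genotype_table()].
#' @param popmap named character vector individual -> population.
#' @param locus locus id.
#' @param population population label.
#' @param mode `"diploid"` or `"multicopy"`.
#' @return list of class `allele_spectrum`: `locus`, `population`, `counts`
#'   (named numeric), `freqs`, `n` (total gene-copy counts), `mode`,
#'   `n_individuals` (with at least one scored allele).
#' @export
allele_frequencies <- function(gt, popmap, locus, population,
                               mode = c("diploid", "multicopy")) {
  mode <- match.arg(mode)
  kind <- gt$loci$kind[gt$loci$locus_id == locus]
  if (length(kind) != 1L) stop("unknown locus ", locus)
  if (mode == "multicopy" && kind != "sequence_multicopy")
    stop("multicopy mode requires a sequence_multicopy locus")
  inds <- gt$individuals[popmap[gt$individuals] == population]
  if (length(inds) == 0L) stop("empty population ", population)
  counts <- numeric(0)
  n_ind <- 0L
  add <- function(counts, a, w) {
    i <- match(a, names(counts))
    if (is.na(i)) counts[[a]] <- w else counts[[i]] <- counts[[i]] + w
    counts
  }
  for (ind in inds) {
    raw <- gt$calls[[locus]][[match(ind, gt$individuals)]]
    cc <- raw[!is.na(raw)]
    if (length(cc) == 0L) next
    n_ind <- n_ind + 1L
    if (mode == "multicopy") {
      u <- unique(cc)
      if (length(u) == 1L) counts <- add(counts, u, 2)
      else for (a in u) counts <- add(counts, a, 1)
    } else {
      if (kind == "sequence_diploid" && length(raw) == 1L) cc <- rep(cc, 2L)
      for (a in cc) counts <- add(counts, a, 1)
    }
  }
  if (length(counts) == 0L) stop("no scored alleles in population ", population)
  counts <- counts[order(names(counts))]
  n <- sum(counts)
  structure(list(locus = locus, population = population, counts = counts,
                 freqs = counts / n, n = n, mode = mode,
                 n_individuals = n_ind),
            class = "allele_spectrum")
}

#' Rarefied allelic richness
#'
#' Hypergeometric expectation of the number of distinct alleles in a
#' subsample of `g` gene copies: `A_g = sum_i [1 - C(n - n_i, g) / C(n, g)]`.
#'
#' @param spectrum an `allele_spectrum` (or a named count vector).
#' @param g rarefaction size in gene copies, `1 <= g <= n`.
#' @return expected allele count (equals the observed count at `g = n`).
#' @export
allelic_richness_rarefied <- function(spectrum, g) {
  counts <- if (inherits(spectrum, "allele_spectrum")) spectrum$counts
            else spectrum
  n <- sum(counts)
  if (g > n || g < 1L) stop("rarefaction size g must lie in [1, n]")
  sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
}

#' Expected and observed heterozygosity
#'
#' @param spectrum an `allele_spectrum`.
#' @param genotypes optional list of the population's diploid calls, used
#'   for observed heterozygosity (fraction of complete genotypes carrying
#'   two distinct alleles); `H_O` is `NA` (flagged) in multicopy mode.
#' @return list with `H_E` (plain, 1 - sum p^2), `H_E_unbiased`
#'   (n/(n-1)-corrected), `H_O`, `n`.
#' @export
heterozygosity <- function(spectrum, genotypes = NULL) {
  n <- spectrum$n
  if (n < 2) stop("need at least 2 gene copies")
  he <- 1 - sum(spectrum$freqs^2)
  ho <- NA_real_
  if (spectrum$mode == "diploid" && !is.null(genotypes)) {
    ok <- genotypes[lengths(genotypes) >= 1L &
                      !vapply(genotypes, anyNA, TRUE)]
    if (length(ok))
      ho <- mean(vapply(ok, function(g) length(unique(g)) > 1L, TRUE))
  }
  list(H_E = he, H_E_unbiased = he * n / (n - 1), H_O = ho, n = n)
}

# pairwise difference counts between alleles of an alignment, over the
# analyzed (indel-free) columns only
allele_diff_matrix <- function(aln) {
  keep <- setdiff(seq_len(aln$alignment_length), aln$indel_columns)
  if (length(keep) < 1L)
    stop("no analyzed sites: alignment is all indel columns")
  m <- aln$seq_matrix[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$allele_ids, aln$allele_ids))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  d
}

#' Sequence diversity statistics for one population sample
#'
#' Computes, over gene copies: the number of segregating sites `S` (analyzed
#' columns only), indel base pairs, the mean number of pairwise nucleotide
#' differences `k`, haplotype diversity `H_D = n/(n-1) (1 - sum p_h^2)` with
#' Nei's sampling SD, and nucleotide diversity `pi = k / analyzed_sites`
#' with Nei's SD.  Haplotype identity retains indel state (distinct gap
#' patterns are distinct alleles); nucleotide comparisons exclude every
#' indel column (complete deletion).
#'
#' @param aln a [locus_alignment()].
#' @param copies character vector of allele ids, one entry per gene copy in
#'   the population sample (duplicates expected).
#' @param n_boot optional bootstrap replicates over individuals for
#'   empirical SDs of `H_D` and `pi` (requires `copies_by_individual`).
#' @param copies_by_individual optional list grouping `copies` by individual.
#' @param seed seed for the bootstrap.
#' @return list with `n`, `S`, `indel_bp`, `k`, `pi`, `H_D`, `H_D_sd`,
#'   `pi_sd`, `analyzed_sites`, and bootstrap SDs when requested.
#' @export
seq_diversity_stats <- function(aln, copies, n_boot = 0L,
                                copies_by_individual = NULL, seed = 1L) {
  n <- length(copies)
  if (n < 2L) stop("need at least 2 gene copies")
  bad <- setdiff(unique(copies), aln$allele_ids)
  if (length(bad)) stop("unknown allele id(s): ", paste(bad, collapse = ", "))
  L <- aln$analyzed_sites
  dmat <- allele_diff_matrix(aln)
  core <- function(copies) {
    n <- length(copies)
    cnt <- table(copies)
    p <- as.numeric(cnt) / n
    ids <- names(cnt)
    # k: mean pairwise differences over all C(n,2) copy pairs
    cm <- as.numeric(cnt)
    dsub <- dmat[ids, ids, drop = FALSE]
    tot <- (sum((cm %o% cm) * dsub) / 2)  # within-identical pairs add 0
    k <- tot / choose(n, 2)
    # S among the present alleles
    keep <- setdiff(seq_len(aln$alignment_length), aln$indel_columns)
    m <- aln$seq_matrix[match(ids, aln$allele_ids), keep, drop = FALSE]
    S <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
    sum_p2 <- sum(p^2)
    hd <- n / (n - 1) * (1 - sum_p2)
    list(n = n, S = S, k = k, pi = k / L, H_D = hd, p = p,
         sum_p2 = sum_p2)
  }
  st <- core(copies)
  # Nei (1987) sampling variances
  p <- st$p; sp2 <- st$sum_p2
  v_hd <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sp2^2) + sp2 - sp2^2)
  v_pi <- (n + 1) / (3 * (n - 1) * L) * st$pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * st$pi^2
  out <- list(n = n, S = st$S, indel_bp = length(aln$indel_columns),
              k = st$k, pi = st$pi, H_D = st$H_D,
              H_D_sd = sqrt(max(v_hd, 0)), pi_sd = sqrt(max(v_pi, 0)),
              analyzed_sites = L)
  if (n_boot > 0L) {
    if (is.null(copies_by_individual))
      stop("bootstrap SDs require copies_by_individual")
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      grp <- copies_by_individual[sample.int(length(copies_by_individual),
                                             replace = TRUE)]
      cc <- unlist(grp, use.names = FALSE)
      if (length(unique(cc)) < 1L || length(cc) < 2L) return(c(NA, NA))
      s <- core(cc)
      c(s$H_D, s$pi)
    }, numeric(2L))
    out$H_D_sd_boot <- sd(reps[1L, ], na.rm = TRUE)
    out$pi_sd_boot <- sd(reps[2L, ], na.rm = TRUE)
  }
  out
}

# Dice similarity between two allele multisets
dice_similarity <- function(x, y) {
  shared <- 0L
  pool <- y
  for (a in x) {
    j <- match(a, pool)
    if (!is.na(j)) { shared <- shared + 1L; pool <- pool[-j] }
  }
  2 * shared / (length(x) + length(y))
}

# per-individual allele multisets at a locus (diploid homozygote = allele
# twice; multicopy = the distinct allele set; half-locus = the scored allele)
allele_multisets <- function(gt, locus, individuals) {
  kind <- gt$loci$kind[gt$loci$locus_id == locus]
  idx <- match(individuals, gt$individuals)
  lapply(gt$calls[[locus]][idx], function(raw) {
    cc <- raw[!is.na(raw)]
    if (length(cc) == 0L) return(character(0))
    if (kind == "sequence_diploid" && length(raw) == 1L) return(rep(cc, 2L))
    cc
  })
}

#' Average percent difference (APD) within one population
#'
#' For every unordered pair of individuals with allele multisets of sizes
#' `n_x`, `n_y` sharing `n_xy` alleles, the Dice similarity is
#' `S = 2 n_xy / (n_x + n_y)` and the pair percent difference is
#' `100 (1 - S)`; APD is the mean over all `C = N (N - 1) / 2` pairs and the
#' SE is the sample SD of pair values over `sqrt(C)`.  Individuals without
#' any scored allele are excluded with a warning.
#'
#' @param gt a [genotype_table()].
#' @param popmap population map.
#' @param locus locus id.
#' @param population population label.
#' @return data.frame row: `population`, `locus`, `N`, `C`, `APD`, `SE`.
#' @export
apd <- function(gt, popmap, locus, population) {
  inds <- gt$individuals[popmap[gt$individuals] == population]
  sets <- allele_multisets(gt, locus, inds)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " individual(s) without scored alleles excluded")
    sets <- sets[!empty]
  }
  N <- length(sets)
  if (N < 2L) stop("need at least 2 individuals with scored alleles")
  vals <- pair_percent_differences(sets)
  data.frame(population = population, locus = locus, N = N,
             C = length(vals), APD = mean(vals),
             SE = sd(vals) / sqrt(length(vals)))
}

# all pairwise 100*(1 - Dice) values for a list of allele multisets
pair_percent_differences <- function(sets) {
  N <- length(sets)
  vals <- numeric(N * (N - 1) / 2)
  k <- 0L
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    k <- k + 1L
    vals[[k]] <- 100 * (1 - dice_similarity(sets[[i]], sets[[j]]))
  }
  vals
}

#' Assemble a per-population, per-locus diversity table
#'
#' One row per (population, locus) combining allele-frequency indices with
#' sequence indices where an alignment is available (layout of a standard
#' diversity report table).
#'
#' @param gt a [genotype_table()].
#' @param popmap population map.
#' @param rarefy_g optional named vector of rarefaction sizes per locus
#'   (default: smallest per-population gene-copy count across populations).
#' @return data.frame with columns population, locus, N, n_copies, A,
#'   A_CORR, H_O, H_E, S, indel_bp, k, H_D, H_D_sd, pi, pi_sd.
#' @export
diversity_table <- function(gt, popmap, rarefy_g = NULL) {
  pops <- unique(popmap[gt$individuals])
  rows <- list()
  for (li in seq_len(nrow(gt$loci))) {
    locus <- gt$loci$locus_id[[li]]
    kind <- gt$loci$kind[[li]]
    mode <- if (kind == "sequence_multicopy") "multicopy" else "diploid"
    specs <- lapply(pops, function(p)
      allele_frequencies(gt, popmap, locus, p, mode))
    g <- if (!is.null(rarefy_g) && locus %in% names(rarefy_g))
      rarefy_g[[locus]] else min(vapply(specs, function(s) s$n, 0))
    for (pi_ in seq_along(pops)) {
      sp <- specs[[pi_]]
      inds <- gt$individuals[popmap[gt$individuals] == pops[[pi_]]]
      het <- heterozygosity(sp, gt$calls[[locus]][match(inds, gt$individuals)])
      row <- data.frame(population = pops[[pi_]], locus = locus,
                        N = sp$n_individuals, n_copies = sp$n,
                        A = length(sp$counts),
                        A_CORR = allelic_richness_rarefied(sp, min(g, sp$n)),
                        H_O = het$H_O, H_E = het$H_E,
                        S = NA_integer_, indel_bp = NA_integer_,
                        k = NA_real_, H_D = NA_real_, H_D_sd = NA_real_,
                        pi = NA_real_, pi_sd = NA_real_)
      aln <- gt$alignments[[locus]]
      if (!is.null(aln) && kind != "microsatellite") {
        # multicopy loci: sequence indices are computed on the estimated
        # allele counts from the uncertain-copy-number rule (approximation)
        copies <- if (kind == "sequence_diploid") gene_copies(gt, locus, inds)
                  else rep(names(sp$counts), round(sp$counts))
        if (length(copies) >= 2L) {
          sq <- seq_diversity_stats(aln, copies)
          row$S <- sq$S; row$indel_bp <- sq$indel_bp; row$k <- sq$k
          row$H_D <- sq$H_D; row$H_D_sd <- sq$H_D_sd
          row$pi <- sq$pi; row$pi_sd <- sq$pi_sd
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
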
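# Synthetic two-population data generators.
#
# Neutral sequence loci are drawn from a structured (or single-deme)
# coalescent with infinite-sites mutation; time is measured in units of
# 1/(2u) generations so that the expected pairwise difference between two
# copies coalescing at time v is v, per-pair coalescence proceeds at rate
# 1/theta and mutations accrue at rate 1/2 per lineage.  Selected loci use a
# forward-time Wright-Fisher model (overdominance has no simple coalescent).

#' Simulation scenario for the two-population study design
#'
#' Bundles every parameter of the synthetic generator: sample sizes, the
#' microsatellite Wright-Fisher model, neutral sequence loci (intron-like and
#' MHC-exon-like), the selection mode of the balancing locus, the multicopy
#' detection model, the sudden-expansion demography, and the replicate-PCR
#' error model.  Defaults emulate the study design: two populations of ~30-36
#' genotyped individuals, 13 microsatellites, a 668-bp intron carrying 14 bp
#' of indels, a 246-bp single-copy MHC exon and a 205-bp possibly-duplicated
#' MHC locus, with fecal-DNA genotyping error (allelic dropout, false
#' alleles) at per-PCR rates consistent with low consensus-level error.
#'
#' @param n_per_pop integer(2), diploid individuals sampled per population.
#' @param n_msat_loci number of microsatellite loci.
#' @param msat_mu stepwise mutation rate per gamete per generation.
#' @param N_e diploid deme size for forward-time models.
#' @param m migration rate per gene copy per generation (forward models).
#' @param M scaled migration rate 4*N_e*m for the coalescent (two demes).
#' @param seq_loci data.frame of sequence-locus specs: `locus_id`, `kind`,
#'   `length_bp`, `theta` (per-locus 4*N_e*u), `indel_events`,
#'   `indel_total_bp`.
#' @param selection list: `mode` one of `"neutral"`, `"overdominant"`,
#'   `"skewed"`; `s` selection coefficient against homozygotes;
#'   `target_freq` pinned top-allele frequency (skewed mode, deme 1 only).
#' @param multicopy_dropout per-allele-copy detection failure probability at
#'   the multicopy locus.
#' @param expansion list: `tau`, `theta0`, `theta1` of the sudden-expansion
#'   demography (tau in units of 2*u*t).
#' @param error list: `dropout` per-PCR allelic dropout rate and
#'   `false_allele` per-PCR false-allele rate.
#' @param seed master seed; every generator derives its stream from it.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_per_pop = c(36L, 31L),
                         n_msat_loci = 13L,
                         msat_mu = 1e-3,
                         N_e = 500L,
                         m = 0.002,
                         M = 4,
                         seq_loci = data.frame(
                           locus_id = c("intron", "mhc_exon", "mhc_multi"),
                           kind = c("sequence_diploid", "sequence_diploid",
                                    "sequence_multicopy"),
                           length_bp = c(668L, 246L, 205L),
                           theta = c(1.0, 2.3, 8),
                           indel_events = c(2L, 0L, 0L),
                           indel_total_bp = c(14L, 0L, 0L)),
                         selection = list(mode = "overdominant", s = 0.3,
                                          target_freq = 0.44),
                         multicopy_dropout = 0.15,
                         expansion = list(tau = 5, theta0 = 1, theta1 = 100),
                         error = list(dropout = 0.05, false_allele = 0.01),
                         seed = 1L) {
  rates <- c(msat_mu, m, multicopy_dropout, error$dropout, error$false_allele)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!is.null(selection$s) && (selection$s < 0 || selection$s > 1))
    stop("selection coefficient s must lie in [0, 1]")
  if (expansion$tau < 0) stop("tau must be non-negative")
  if (any(N_e < n_per_pop)) stop("N_e must be at least the sample size")
  structure(list(n_per_pop = as.integer(n_per_pop),
                 n_msat_loci = as.integer(n_msat_loci), msat_mu = msat_mu,
                 N_e = as.integer(N_e), m = m, M = M, seq_loci = seq_loci,
                 selection = selection, multicopy_dropout = multicopy_dropout,
                 expansion = expansion, error = error, seed = seed),
            class = "sim_scenario")
}

# ---- coalescent engine -------------------------------------------------------

# Structured coalescent genealogy for n_per_deme gene copies.  theta_fun(v)
# gives theta at (backwards) time v; tau_break marks its single discontinuity
# (Inf for constant size).  M is the scaled migration rate 4*N*m (per-lineage
# migration rate M/(2*theta)).  Returns node times and parent pointers; tips
# are nodes 1..n, carrying deme labels in tip_deme.
coal_genealogy <- function(n_per_deme, theta, M = 0, tau_break = Inf,
                           theta_old = theta) {
  n <- sum(n_per_deme)
  n_demes <- length(n_per_deme)
  if (n_demes > 1L && M <= 0)
    stop("two-deme coalescent requires positive migration rate M")
  deme <- rep(seq_len(n_demes), n_per_deme)
  active <- seq_len(n)
  node_time <- numeric(2L * n - 1L)
  parent <- integer(2L * n - 1L)
  nxt <- n + 1L
  v <- 0
  # floor theta so a zero-size epoch behaves as (numerically) instantaneous
  # coalescence instead of producing infinite rates
  th <- function(v) max(if (v < tau_break) theta else theta_old, 1e-8)
  while (length(active) > 1L) {
    k_d <- tabulate(deme[active], n_demes)
    coal_rates <- k_d * (k_d - 1) / 2 / th(v)
    mig_rate <- if (n_demes > 1L) sum(k_d) * M / (2 * th(v)) else 0
    tot <- sum(coal_rates) + mig_rate
    dt <- rexp(1L, tot)
    if (v < tau_break && v + dt > tau_break && theta != theta_old) {
      v <- tau_break          # rates change at the size shift; redraw
      tau_break <- Inf
      theta <- theta_old
      next
    }
    v <- v + dt
    if (runif(1L) < mig_rate / tot) {
      i <- active[[sample.int(length(active), 1L)]]
      deme[[i]] <- if (n_demes == 2L) 3L - deme[[i]] else
        sample(setdiff(seq_len(n_demes), deme[[i]]), 1L)
    } else {
      d <- sample.int(n_demes, 1L, prob = coal_rates)
      in_d <- active[deme[active] == d]
      pair <- in_d[sample.int(length(in_d), 2L)]
      node_time[[nxt]] <- v
      parent[pair] <- nxt
      deme[[nxt]] <- d
      active <- c(setdiff(active, pair), nxt)
      nxt <- nxt + 1L
    }
  }
  list(n = n, node_time = node_time, parent = parent,
       tip_deme = rep(seq_len(n_demes), n_per_deme))
}

# Descendant tips of each internal branch; returns a list indexed by node.
branch_tips <- function(gen) {
  n_nodes <- 2L * gen$n - 1L
  tips <- vector("list", n_nodes)
  for (i in seq_len(gen$n)) tips[[i]] <- i
  ord <- order(gen$node_time[seq_len(n_nodes)])
  for (i in ord) {
    p <- gen$parent[[i]]
    if (p > 0L) tips[[p]] <- c(tips[[p]], tips[[i]])
  }
  tips
}

# Drop infinite-sites mutations on a genealogy (rate 1/2 per lineage per unit
# time) and return, per mutation, the set of carrier tips.
mutation_carriers <- function(gen) {
  n_nodes <- 2L * gen$n - 1L
  root <- which(gen$parent == 0L & seq_len(n_nodes) <= n_nodes)
  root <- root[which.max(gen$node_time[root])]
  blen <- numeric(n_nodes)
  nz <- gen$parent > 0L
  blen[nz] <- gen$node_time[gen$parent[nz]] - gen$node_time[seq_len(n_nodes)][nz]
  blen[blen < 0] <- 0
  n_mut <- rpois(n_nodes, blen / 2)
  tips <- branch_tips(gen)
  carriers <- list()
  for (i in seq_len(n_nodes)) {
    if (i == root || n_mut[[i]] == 0L) next
    for (j in seq_len(n_mut[[i]])) carriers[[length(carriers) + 1L]] <- tips[[i]]
  }
  carriers
}

BASES <- c("A", "C", "G", "T")

# Convert mutation carrier sets into aligned sequences of length L.
# Transitions are drawn with probability ts_prob (so K2P-style data can be
# generated); indel events, if any, convert whole mutation events into gap
# runs whose widths sum to indel_total_bp.
seqs_from_mutations <- function(n, L, carriers, indel_events = 0L,
                                indel_total_bp = 0L, ts_prob = 0.7) {
  S <- length(carriers)
  n_indel <- min(indel_events, S)
  widths <- integer(0)
  if (n_indel > 0L) {
    widths <- rep(indel_total_bp %/% n_indel, n_indel)
    widths[[1L]] <- widths[[1L]] + indel_total_bp %% n_indel
  }
  need <- (S - n_indel) + sum(widths)
  if (need > L)
    stop("requested segregating sites (", need,
         ") exceed sequence capacity L = ", L)
  ref <- sample(BASES, L, replace = TRUE)
  mat <- matrix(rep(ref, each = n), nrow = n)
  pos <- sample.int(L, need)
  used <- 0L
  which_indel <- if (n_indel > 0L) sample.int(S, n_indel) else integer(0)
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (s in seq_len(S)) {
    tips <- carriers[[s]]
    if (s %in% which_indel) {
      w <- widths[[match(s, which_indel)]]
      cols <- pos[(used + 1L):(used + w)]
      used <- used + w
      mat[tips, cols] <- "-"
    } else {
      col <- pos[[used + 1L]]
      used <- used + 1L
      anc <- ref[[col]]
      der <- if (runif(1L) < ts_prob) ts_of[[anc]] else
        sample(setdiff(BASES, c(anc, ts_of[[anc]])), 1L)
      mat[tips, col] <- der
    }
  }
  apply(mat, 1L, paste, collapse = "")
}

# ---- neutral sequence loci ---------------------------------------------------

#' Simulate one sequence locus in one or two demes (neutral coalescent)
#'
#' Samples `2 * n_per_pop` gene copies per deme from a symmetric-migration
#' structured coalescent with infinite-sites mutation, collapses identical
#' haplotypes to alleles, and pairs copies at random within demes into
#' diploid genotypes.
#'
#' @param scenario a [sim_scenario()].
#' @param locus_id which row of `scenario$seq_loci` to simulate.
#' @param n_demes 1 or 2.
#' @param seed integer seed (defaults to a stream derived from the scenario
#'   master seed).
#' @return list with `alignment` (a [locus_alignment()] of the distinct
#'   alleles), `genotypes` (a [genotype_table()]), `popmap`, and `copies`
#'   (the per-copy allele ids, for oracle checks).
#' @export
simulate_seq_two_pop <- function(scenario, locus_id = "intron", n_demes = 2L,
                                 seed = NULL) {
  spec <- scenario$seq_loci[scenario$seq_loci$locus_id == locus_id, ]
  if (nrow(spec) != 1L) stop("unknown sequence locus ", locus_id)
  if (is.null(seed)) seed <- derive_seed(scenario$seed, 11L)
  set.seed(seed)
  n_pp <- scenario$n_per_pop[seq_len(n_demes)]
  gen <- coal_genealogy(2L * n_pp, theta = spec$theta, M = scenario$M)
  carriers <- mutation_carriers(gen)
  seqs <- seqs_from_mutations(gen$n, spec$length_bp, carriers,
                              spec$indel_events, spec$indel_total_bp)
  build_seq_locus(locus_id, spec$kind, seqs, n_pp)
}

# Collapse per-copy sequences into an allele alignment + diploid genotypes.
build_seq_locus <- function(locus_id, kind, seqs, n_pp) {
  uniq <- unique(seqs)
  ids <- sprintf("%s*%02d", locus_id, seq_along(uniq))
  copy_allele <- ids[match(seqs, uniq)]
  aln <- locus_alignment(locus_id, ids, uniq)
  n_tot <- sum(n_pp)
  inds <- sprintf("ind_%03d", seq_len(n_tot))
  popmap <- setNames(rep(paste0("pop", seq_along(n_pp)), n_pp), inds)
  calls <- vector("list", n_tot)
  off <- 0L
  ind_i <- 0L
  for (d in seq_along(n_pp)) {
    copies <- copy_allele[off + seq_len(2L * n_pp[[d]])]
    perm <- sample(copies)   # random pairing within deme
    for (j in seq_len(n_pp[[d]])) {
      ind_i <- ind_i + 1L
      pair <- perm[c(2L * j - 1L, 2L * j)]
      calls[[ind_i]] <- unique(pair)
    }
    off <- off + 2L * n_pp[[d]]
  }
  gt <- genotype_table(inds,
                       data.frame(locus_id = locus_id, kind = "sequence_diploid"),
                       setNames(list(calls), locus_id),
                       alignments = setNames(list(aln), locus_id))
  list(alignment = aln, genotypes = gt, popmap = popmap, copies = copy_allele)
}

# ---- microsatellites ---------------------------------------------------------

#' Simulate diploid microsatellite genotypes in two demes (forward-time)
#'
#' Finite-island Wright-Fisher with stepwise mutation: each deme holds
#' `2 * N_e` gene copies; every generation each copy picks a parent copy from
#' its own deme with probability `1 - m` (otherwise the other deme) and
#' mutates by one repeat unit with probability `msat_mu`.  Burn-in is
#' `10 * N_e` generations from a monomorphic start.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @param burnin_factor generations of burn-in per unit `N_e`.
#' @return list with `genotypes` (microsatellite [genotype_table()]) and
#'   `popmap`.
#' @export
simulate_msat_two_pop <- function(scenario, seed = NULL, burnin_factor = 10) {
  if (is.null(seed)) seed <- derive_seed(scenario$seed, 21L)
  set.seed(seed)
  N <- scenario$N_e
  L <- scenario$n_msat_loci
  m <- scenario$m
  mu <- scenario$msat_mu
  n2 <- 2L * N
  pool <- list(matrix(120L, n2, L), matrix(120L, n2, L))
  gens <- ceiling(burnin_factor * N)
  for (g in seq_len(gens)) {
    new_pool <- pool
    for (d in 1:2) {
      other <- 3L - d
      from_other <- matrix(runif(n2 * L) < m, n2, L)
      idx_own <- matrix(sample.int(n2, n2 * L, replace = TRUE), n2, L)
      idx_oth <- matrix(sample.int(n2, n2 * L, replace = TRUE), n2, L)
      child <- pool[[d]][cbind(as.vector(idx_own), rep(seq_len(L), each = n2))]
      child <- matrix(child, n2, L)
      if (m > 0) {
        oth <- pool[[other]][cbind(as.vector(idx_oth),
                                   rep(seq_len(L), each = n2))]
        oth <- matrix(oth, n2, L)
        child[from_other] <- oth[from_other]
      }
      mut <- matrix(runif(n2 * L) < mu, n2, L)
      if (any(mut))
        child[mut] <- child[mut] + sample(c(-1L, 1L), sum(mut), replace = TRUE)
      new_pool[[d]] <- child
    }
    pool <- new_pool
  }
  n_pp <- scenario$n_per_pop
  inds <- sprintf("ind_%03d", seq_len(sum(n_pp)))
  popmap <- setNames(rep(c("pop1", "pop2"), n_pp), inds)
  loci <- data.frame(locus_id = sprintf("msat%02d", seq_len(L)),
                     kind = "microsatellite")
  calls <- setNames(vector("list", L), loci$locus_id)
  for (l in seq_len(L)) {
    cl <- vector("list", sum(n_pp))
    k <- 0L
    for (d in 1:2) {
      rows <- sample.int(n2, 2L * n_pp[[d]])
      for (j in seq_len(n_pp[[d]])) {
        k <- k + 1L
        cl[[k]] <- as.character(pool[[d]][rows[c(2L * j - 1L, 2L * j)], l])
      }
    }
    calls[[l]] <- cl
  }
  list(genotypes = genotype_table(inds, loci, calls), popmap = popmap)
}

# ---- balancing-selection locus ----------------------------------------------

#' Simulate an MHC-like locus under selection (forward-time, two demes)
#'
#' Multiallelic symmetric overdominance: heterozygotes have fitness 1 and
#' homozygotes 1 - s, in both demes, with infinite-alleles mutation and
#' migration.  The `"skewed"` mode instead applies, in deme 1 only, a
#' frequency-stabilizing weight that holds one focal allele near
#' `target_freq` (a phenomenological stand-in for spatially heterogeneous
#' selection); deme 2 evolves neutrally.  `"neutral"` sets s = 0.
#'
#' @param scenario a [sim_scenario()]; uses `selection`, `N_e`, `m`.
#' @param locus_id sequence-locus spec row used for allele sequence lengths.
#' @param seed integer seed.
#' @param generations forward generations (default `10 * N_e`).
#' @param mu infinite-alleles mutation rate per gamete.
#' @param K_init initial number of alleles.
#' @return as [simulate_seq_two_pop()]: alignment + diploid genotypes +
#'   popmap + copies.
#' @export
simulate_balancing_locus <- function(scenario, locus_id = "mhc_exon",
                                     seed = NULL, generations = NULL,
                                     mu = 1e-4, K_init = 10L) {
  sel <- scenario$selection
  if (sel$mode == "overdominant" && (sel$s < 0 || sel$s > 1))
    stop("selection coefficient s must lie in [0, 1]")
  spec <- scenario$seq_loci[scenario$seq_loci$locus_id == locus_id, ]
  if (nrow(spec) != 1L) stop("unknown sequence locus ", locus_id)
  if (is.null(seed)) seed <- derive_seed(scenario$seed, 31L)
  set.seed(seed)
  N <- scenario$N_e
  m <- scenario$m
  gens <- if (is.null(generations)) 10L * N else generations
  # skewed mode keeps heterozygote advantage (so non-focal alleles stay
  # evenly spread, as in the unpinned deme) and adds the deme-1 pin
  s <- switch(sel$mode, neutral = 0, skewed = sel$s, overdominant = sel$s)
  # allele matrices: rows = individuals, cols = two gene copies, per deme
  al <- list(matrix(sample.int(K_init, 2L * N, replace = TRUE), N, 2L),
             matrix(sample.int(K_init, 2L * N, replace = TRUE), N, 2L))
  next_allele <- K_init + 1L
  for (g in seq_len(gens)) {
    new_al <- al
    for (d in 1:2) {
      w <- ifelse(al[[d]][, 1L] == al[[d]][, 2L], 1 - s, 1)
      other <- 3L - d
      p1 <- sample.int(N, N, replace = TRUE, prob = w)
      p2 <- sample.int(N, N, replace = TRUE, prob = w)
      gam1 <- al[[d]][cbind(p1, sample.int(2L, N, replace = TRUE))]
      gam2 <- al[[d]][cbind(p2, sample.int(2L, N, replace = TRUE))]
      if (m > 0) {
        mig <- runif(N) < m
        n_mig <- sum(mig)
        if (n_mig > 0L) {
          po <- sample.int(N, n_mig, replace = TRUE)
          gam1[mig] <- al[[other]][cbind(po, sample.int(2L, n_mig,
                                                        replace = TRUE))]
        }
        mig <- runif(N) < m
        n_mig <- sum(mig)
        if (n_mig > 0L) {
          po <- sample.int(N, n_mig, replace = TRUE)
          gam2[mig] <- al[[other]][cbind(po, sample.int(2L, n_mig,
                                                        replace = TRUE))]
        }
      }
      for (gam in c("gam1", "gam2")) {
        gg <- get(gam)
        mut <- runif(N) < mu
        if (any(mut)) {
          gg[mut] <- next_allele - 1L + seq_len(sum(mut))
          next_allele <- next_allele + sum(mut)
          assign(gam, gg)
        }
      }
      new_al[[d]] <- cbind(gam1, gam2)
      if (sel$mode == "skewed" && d == 1L) {
        # pin the focal allele (id 1) at target_freq in deme 1 by converting
        # gametes to/from the rest of the pool (sampled data remain noisy;
        # the census frequency is held at the target)
        pool <- as.vector(new_al[[1L]])
        k_tgt <- round(2L * N * sel$target_freq)
        cur <- sum(pool == 1L)
        if (cur > k_tgt) {
          donors <- pool[pool != 1L]
          if (length(donors) > 0L) {
            idx <- sample(which(pool == 1L), cur - k_tgt)
            pool[idx] <- donors[sample.int(length(donors), cur - k_tgt,
                                           replace = TRUE)]
          }
        } else if (cur < k_tgt) {
          idx <- sample(which(pool != 1L), min(k_tgt - cur,
                                               sum(pool != 1L)))
          pool[idx] <- 1L
        }
        new_al[[1L]] <- matrix(pool, N, 2L)
      }
    }
    al <- new_al
  }
  n_pp <- scenario$n_per_pop
  focal_freq <- c(mean(al[[1L]] == 1L), mean(al[[2L]] == 1L))
  copies <- integer(0)
  for (d in 1:2) {
    rows <- sample.int(N, n_pp[[d]])
    copies <- c(copies, as.vector(t(al[[d]][rows, , drop = FALSE])))
  }
  # relabel surviving alleles and attach random divergent sequences
  surv <- sort(unique(copies))
  lab <- match(copies, surv)
  ref <- sample(BASES, spec$length_bp, replace = TRUE)
  seqs_allele <- vapply(seq_along(surv), function(i) {
    s_ <- ref
    hit <- runif(spec$length_bp) < 0.05
    s_[hit] <- vapply(s_[hit], function(b) sample(setdiff(BASES, b), 1L), "")
    paste(s_, collapse = "")
  }, "")
  seqs <- seqs_allele[lab]
  out <- build_seq_locus(locus_id, "sequence_diploid", seqs, n_pp)
  # census (whole-deme) frequency of the focal allele, per deme; the focal
  # allele is the one pinned in skewed mode
  out$focal_freq <- focal_freq
  out$focal_present <- 1L %in% surv
  out
}

# ---- multicopy locus ---------------------------------------------------------

#' Derive multicopy (1-4 allele) genotypes from two diploid base loci
#'
#' Emulates a possibly-duplicated locus whose primers amplify two underlying
#' loci: the four gene copies of each individual (two per base locus) are
#' pooled, each copy is detected independently with probability
#' `1 - multicopy_dropout`, and the distinct detected allele ids form the
#' call (0 detected alleles is emitted as missing).
#'
#' @param scenario a [sim_scenario()] (supplies `multicopy_dropout`).
#' @param base a [genotype_table()] with at least two sequence_diploid loci.
#' @param loci character(2): the two base loci to pair.
#' @param locus_id id of the derived multicopy locus.
#' @param seed integer seed.
#' @return a [genotype_table()] with one sequence_multicopy locus.
#' @export
simulate_multicopy_genotypes <- function(scenario, base,
                                         loci = head(base$loci$locus_id, 2L),
                                         locus_id = "mhc_multi", seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(scenario$seed, 41L)
  set.seed(seed)
  d <- scenario$multicopy_dropout
  calls <- lapply(seq_along(base$individuals), function(i) {
    cps <- character(0)
    for (l in loci) {
      raw <- base$calls[[l]][[i]]
      cc <- raw[!is.na(raw)]
      if (length(cc) == 0L) next
      if (length(raw) == 1L) cc <- rep(cc, 2L)
      cps <- c(cps, paste0(l, ":", cc))
    }
    detected <- cps[runif(length(cps)) >= d]
    unique(detected)
  })
  genotype_table(base$individuals,
                 data.frame(locus_id = locus_id, kind = "sequence_multicopy"),
                 setNames(list(calls), locus_id))
}

#' Simulate a full two-population study dataset
#'
#' Assembles the complete design in one call: microsatellites (forward
#' Wright-Fisher), a neutral intron (coalescent), an MHC-like exon under
#' the scenario's selection mode (forward-time), and a multicopy MHC locus
#' derived from the exon plus a second coalescent locus by detection
#' dropout.
#'
#' @param scenario a [sim_scenario()].
#' @param seed master seed (defaults to `scenario$seed`).
#' @param msat_burnin burn-in factor for the microsatellite model.
#' @param sel_generations forward generations for the selected locus.
#' @return list with `genotypes` (one [genotype_table()] with all loci and
#'   alignments attached), `popmap`, and the per-component results.
#' @export
simulate_study_dataset <- function(scenario, seed = scenario$seed,
                                   msat_burnin = 10,
                                   sel_generations = NULL) {
  ms <- simulate_msat_two_pop(scenario, seed = derive_seed(seed, 1L),
                              burnin_factor = msat_burnin)
  intr <- simulate_seq_two_pop(scenario, "intron",
                               seed = derive_seed(seed, 2L))
  mhc <- simulate_balancing_locus(scenario, "mhc_exon",
                                  seed = derive_seed(seed, 3L),
                                  generations = sel_generations)
  # two same-length coalescent loci behind the duplicated MHC locus
  auxA <- simulate_seq_two_pop(scenario, "mhc_multi",
                               seed = derive_seed(seed, 4L))
  auxB <- simulate_seq_two_pop(scenario, "mhc_multi",
                               seed = derive_seed(seed, 5L))
  base <- genotype_table(
    mhc$genotypes$individuals,
    data.frame(locus_id = c("mhcA", "mhcB"),
               kind = "sequence_diploid"),
    list(mhcA = auxA$genotypes$calls$mhc_multi,
         mhcB = auxB$genotypes$calls$mhc_multi))
  multi <- simulate_multicopy_genotypes(scenario, base,
                                        loci = c("mhcA", "mhcB"),
                                        seed = derive_seed(seed, 6L))
  multi_aln <- locus_alignment(
    "mhc_multi",
    c(paste0("mhcA:", auxA$alignment$allele_ids),
      paste0("mhcB:", auxB$alignment$allele_ids)),
    c(auxA$alignment$seqs, auxB$alignment$seqs))
  gt <- genotype_table(
    ms$genotypes$individuals,
    rbind(ms$genotypes$loci, intr$genotypes$loci, mhc$genotypes$loci,
          multi$loci),
    c(ms$genotypes$calls, intr$genotypes$calls, mhc$genotypes$calls,
      multi$calls["mhc_multi"]))
  gt$alignments <- c(intr$genotypes$alignments, mhc$genotypes$alignments,
                     setNames(list(multi_aln), "mhc_multi"))
  list(genotypes = gt, popmap = ms$popmap, msat = ms, intron = intr,
       mhc = mhc, multicopy = multi)
}

# ---- replicate-PCR error model ----------------------------------------------

#' Generate replicate-PCR call tables with dropout and false alleles
#'
#' Per PCR and heterozygous genotype, each true allele fails to amplify
#' independently with the dropout rate (one surviving allele is read as a
#' homozygote; both failing gives a missing call).  Independently, with the
#' false-allele rate one allele slot of the read is replaced by a spurious
#' neighbouring-size allele.
#'
#' @param truth microsatellite [genotype_table()].
#' @param error list with `dropout` and `false_allele` per-PCR rates.
#' @param n_pcr number of replicate PCRs per individual and locus.
#' @param seed integer seed.
#' @return object of class `replicate_calls`: list with `individuals`,
#'   `loci`, and `calls[[locus]][[individual]]` = list of per-PCR length-2
#'   allele vectors (`character(0)` = failed PCR).
#' @export
generate_pcr_replicates <- function(truth, error, n_pcr, seed = 1L) {
  set.seed(seed)
  drop <- error$dropout
  fa <- error$false_allele
  calls <- lapply(truth$loci$locus_id, function(l) {
    lapply(seq_along(truth$individuals), function(i) {
      g <- truth$calls[[l]][[i]]
      g <- g[!is.na(g)]
      if (length(g) == 0L) return(vector("list", 0L))
      if (length(g) == 1L) g <- rep(g, 2L)
      lapply(seq_len(n_pcr), function(p) {
        obs <- g
        if (obs[[1L]] != obs[[2L]]) {
          kept <- obs[runif(2L) >= drop]
          if (length(kept) == 0L) return(character(0))
          if (length(kept) == 1L) obs <- rep(kept, 2L) else obs <- kept
        }
        if (runif(1L) < fa) {
          slot <- sample.int(2L, 1L)
          sz <- suppressWarnings(as.integer(obs[[slot]]))
          obs[[slot]] <- if (is.na(sz)) paste0(obs[[slot]], "_fa") else
            as.character(sz + sample(c(-2L, 2L), 1L))
        }
        sort(obs)
      })
    })
  })
  structure(list(individuals = truth$individuals, loci = truth$loci,
                 calls = setNames(calls, truth$loci$locus_id)),
            class = "replicate_calls")
}

#' Write replicate calls as a long-format TSV
#' @param rc a `replicate_calls` object.
#' @param path output TSV (individual, locus, pcr_index, allele1, allele2).
#' @export
write_replicate_calls <- function(rc, path) {
  rows <- list()
  for (l in rc$loci$locus_id) for (i in seq_along(rc$individuals)) {
    pcrs <- rc$calls[[l]][[i]]
    for (p in seq_along(pcrs)) {
      g <- pcrs[[p]]
      rows[[length(rows) + 1L]] <- data.frame(
        individual = rc$individuals[[i]], locus = l, pcr_index = p,
        allele1 = if (length(g)) g[[1L]] else "NA",
        allele2 = if (length(g)) g[[2L]] else "NA")
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- sudden expansion --------------------------------------------------------

#' Simulate haplotypes under a sudden demographic expansion
#'
#' Single-deme coalescent whose (backwards-time) mutation-scaled size
#' shifts from `theta1` (present) to `theta0` (ancestral) at time `tau`
#' (units of 2*u*t), with infinite-sites mutation.  Returns one FASTA record
#' per sampled gene copy (duplicates retained), the input of the mismatch
#' analyses.
#'
#' @param scenario a [sim_scenario()] (supplies `expansion` and lengths).
#' @param n_copies gene copies to sample.
#' @param length_bp sequence length.
#' @param seed integer seed.
#' @return a [locus_alignment()] with `n_copies` records.
#' @export
simulate_expansion <- function(scenario, n_copies = 50L, length_bp = 668L,
                               seed = NULL) {
  ex <- scenario$expansion
  if (ex$tau < 0) stop("tau must be non-negative")
  if (is.null(seed)) seed <- derive_seed(scenario$seed, 51L)
  set.seed(seed)
  gen <- coal_genealogy(n_copies, theta = ex$theta1, M = 0,
                        tau_break = ex$tau, theta_old = ex$theta0)
  carriers <- mutation_carriers(gen)
  seqs <- seqs_from_mutations(gen$n, length_bp, carriers)
  locus_alignment("expansion", sprintf("copy_%03d", seq_len(n_copies)), seqs)
}
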
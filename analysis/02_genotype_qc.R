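#!/usr/bin/env Rscript
# Replicate-PCR genotyping QC on the simulated microsatellites: generate
# fecal-quality PCR replicates (allelic dropout, false alleles), call
# consensus genotypes by the comparative multi-tubes rule, estimate error
# rates against the simulated truth, and run null-allele EM and exact
# HWE / linkage-disequilibrium checks.  Writes results/qc/*.tsv.

suppressMessages(library(mhccontrast))

seed <- 20260919L
out <- "results/qc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

loci <- read.delim("results/data/loci.tsv")
gt <- read_genotype_table("results/data/genotypes.tsv", loci)
popmap <- read_population_map("results/data/popmap.tsv")
msat <- loci$locus_id[loci$kind == "microsatellite"]
truth <- genotype_table(gt$individuals,
                        loci[loci$kind == "microsatellite", ],
                        gt$calls[msat])

# 5 PCRs per sample at fecal-DNA error rates; consensus from the first
# replicates that satisfy the confirmation rules
rc <- generate_pcr_replicates(truth, list(dropout = 0.05,
                                          false_allele = 0.01),
                              n_pcr = 5, seed = seed)
write_replicate_calls(rc, file.path(out, "replicate_calls.tsv"))
cons <- consensus_genotype_table(rc)
single <- genotype_table(truth$individuals, truth$loci,
                         lapply(rc$calls, function(by_ind)
                           lapply(by_ind, function(x)
                             if (length(x) && length(x[[1]]) == 2) x[[1]]
                             else character(0))))

err_cons <- genotyping_error_rates(truth, cons)
err_single <- genotyping_error_rates(truth, single)

# per-locus HWE (overall and heterozygote-deficiency p), LD between the
# first locus pairs, and null-allele EM within population 1
pop1 <- gt$individuals[popmap[gt$individuals] == unique(popmap)[1]]
hwe <- do.call(rbind, lapply(msat, function(l) {
  g <- cons$calls[[l]][match(pop1, cons$individuals)]
  res <- tryCatch(suppressWarnings(hwe_exact_mc(g, n_mc = 5000,
                                                seed = seed)),
                  error = function(e) list(p = NA, p_het_deficiency = NA,
                                           n = 0))
  naf <- tryCatch(null_allele_em(g)$naf, error = function(e) NA_real_)
  data.frame(locus = l, n = res$n, p_hwe = res$p,
             p_het_deficiency = res$p_het_deficiency, NAF = naf)
}))
hwe$p_hwe_holm <- holm_correction(hwe$p_hwe)$p_adjusted

ld <- do.call(rbind, lapply(seq_len(min(5, length(msat) - 1)), function(i) {
  res <- suppressWarnings(
    ld_permutation_test(cons$calls[[msat[i]]], cons$calls[[msat[i + 1]]],
                        n_perm = 1000, seed = seed + i))
  data.frame(locus1 = msat[i], locus2 = msat[i + 1], G = res$G, p = res$p)
}))

write_summary_tables(list(error_rates_consensus = err_cons,
                          error_rates_single_pcr = err_single,
                          hwe_null_alleles = hwe,
                          linkage_disequilibrium = ld), out)

ov_c <- err_cons$total_error[err_cons$locus == "overall"]
ov_s <- err_single$total_error[err_single$locus == "overall"]
cat(sprintf("Consensus total error %.4f vs single-PCR %.4f (%.0f%% reduction)\n",
            ov_c, ov_s, 100 * (1 - ov_c / ov_s)))
cat("Mean NAF:", round(mean(hwe$NAF, na.rm = TRUE), 4),
    "| HWE rejections after Holm:",
    sum(hwe$p_hwe_holm <= 0.05, na.rm = TRUE), "\n")
cat("QC tables written under", out, "\n")
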
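# mhccontrast

Tools for a question that recurs across wildlife immunogenetics: when two
populations of the same species live under different pathogen regimes, do
their MHC (major histocompatibility complex) loci carry the marks of
balancing or spatially heterogeneous selection once neutral demography is
accounted for?  The package implements the full contrast between neutral
markers (microsatellites, a nuclear intron) and MHC loci in a two-population
design — within-population diversity, between-population differentiation,
neutrality tests, mismatch demography, multicopy-locus allele accounting and
replicate-PCR genotype QC — plus a synthetic two-population generator that
reproduces the statistical structure of such a study, so every stage is
testable end to end.

It is aimed at population geneticists who want these classical statistics as
plain, tested R functions operating on simple containers (FASTA alignments,
TSV genotype tables, a population map) rather than as a chain of GUI tools.

## What is computed

* **Diversity**: allelic richness *A* with hypergeometric rarefaction
  *A*<sub>g</sub> = Σ<sub>i</sub> [1 − C(n−n<sub>i</sub>, g)/C(n, g)];
  *H*<sub>O</sub>, plain and unbiased *H*<sub>E</sub>; *S*, *k*,
  *H*<sub>D</sub> and π = *k*/analyzed sites with Nei sampling SDs; the
  frequency-free APD (mean Dice percent difference over all N(N−1)/2
  individual pairs).
* **Differentiation**: Weir–Cockerham θ (bootstrap CI over loci,
  permutation p), AMOVA Φ<sub>ST</sub> on Kimura-2-parameter distances,
  haplotype-frequency F<sub>ST</sub> (identity distance), Jost's
  *D*<sub>est</sub> (Nei–Chesser estimators, harmonic mean across loci),
  the similarity-based F′ = (S̄<sub>w</sub> − S̄<sub>b</sub>)/(1 −
  S̄<sub>b</sub>), and Raymond–Rousset Markov-chain exact tests.
* **Neutrality**: Tajima's *D* (fixed-*S* coalescent p), Fu's
  *F*<sub>S</sub> (Stirling-number tail probability), and the
  Ewens–Watterson–Slatkin homozygosity test with an exact conditional
  configuration sampler (*F*<sub>obs</sub>, *F*<sub>exp</sub>, lower/upper
  tails and the exact-style *P*<sub>E</sub>).
* **Demography**: mismatch distributions, an exact sudden-expansion law
  F<sub>j</sub>(τ, θ₀, θ₁), least-squares fitting, SSD and raggedness with
  parametric-bootstrap p-values.
* **QC**: comparative multi-tubes consensus genotyping (heterozygotes
  confirmed twice, homozygotes three times, up to 7 PCRs, half-locus
  fallback), allelic-dropout / false-allele / total error rates from paired
  samples, null-allele EM, exact Hardy–Weinberg and genotypic-LD tests.
* **Group comparisons**: Kruskal–Wallis randomization, Levene, rank-sum Z,
  chi-square contingency, Holm correction — orchestrated by
  `run_contrast()`.
* **Simulation**: forward Wright–Fisher microsatellites, a structured
  coalescent with infinite sites and indels, forward-time multiallelic
  overdominance (plus a "skewed" pinned-allele mode), multicopy detection
  dropout, replicate-PCR error, and sudden-expansion samples — all
  bit-reproducible under a seed.

## Worked example

The `analysis/` scripts run the whole study on a simulated dataset:

```sh
Rscript analysis/01_simulate.R          # two populations, 16 loci
Rscript analysis/02_genotype_qc.R       # replicate-PCR consensus + QC
Rscript analysis/03_contrast.R          # diversity/differentiation/neutrality
Rscript analysis/04_mismatch_demography.R
```

On the shipped scenario (MHC exon under symmetric overdominance, s = 0.3)
this prints, among other things:

```
Consensus total error 0.0006 vs single-PCR 0.0362 (98% reduction)
Mean NAF: 0.0179 | HWE rejections after Holm: 0

Differentiation (F_ST / Phi_ST / F' / D_est):
  msat_multilocus  0.157    NA    NA  0.035
  intron           0.146  0.158  0.260  0.165
  mhc_exon         0.032  0.035  0.049  0.149
  mhc_multi          NA    NA  0.104  0.448
MHC exon E-W-S homozygosity: F_obs 0.179/0.211 vs F_exp 0.405/0.393 ; P_H 0.000/0.013
```

Read: the multi-tubes consensus rule pushes fecal-DNA genotyping error to
near zero; the selected MHC exon shows four- to five-fold *lower*
differentiation (F<sub>ST</sub> 0.032 vs 0.146–0.157 at neutral loci) and
significantly lower allele-frequency homozygosity than its neutral
expectation (P<sub>H</sub> ≤ 0.013 in both populations) — the joint
signature of balancing selection.  The mismatch stage recovers a true
sudden expansion (τ = 5 simulated, τ̂ = 4.29 fitted, SSD p = 0.81, i.e. the
expansion model is not rejected) while rejecting it on the stationary
intron data.

All report tables land under `results/` as TSVs whose layouts mirror the
standard diversity / APD / differentiation / neutrality tables of this
study family.

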
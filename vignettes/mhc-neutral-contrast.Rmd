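---
title: "Contrasting neutral and MHC variation in paired populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrasting neutral and MHC variation in paired populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhccontrast)
```

## The scientific question

Balancing selection at immune loci — classically the class II MHC — is
expected to leave three joint signatures when two populations of the same
species are compared against putatively neutral markers: *elevated
within-population diversity*, *more even allele-frequency spectra* (lower
homozygosity than the neutral expectation conditional on the allele count),
and *reduced between-population differentiation*, because selection favouring
rare or heterozygous genotypes raises the effective migration rate of
balanced alleles.  Conversely, spatially heterogeneous selection can skew
one population's spectrum while leaving the other even, producing
*discordant* diversity between populations at the selected locus only.

This package implements the complete analysis pipeline for such a contrast
— diversity, similarity-based and variance-based differentiation,
neutrality tests, mismatch demography, multicopy-locus allele accounting
and replicate-PCR genotype QC — together with a synthetic two-population
generator that reproduces the statistical structure of the study design, so
that every stage is testable end to end without access to individual-level
field data.

## Data model

Four marker classes are supported, mirroring a typical study design:

* **microsatellites** — diploid allele-size pairs, possibly *half-locus*
  calls (one confirmed allele, the other missing) from degraded fecal DNA;
* **a nuclear intron** — diploid sequence locus with indel polymorphism;
  allele identity *includes* the gap pattern, but all pairwise nucleotide
  statistics exclude every column where any haplotype carries a gap
  (complete deletion), so `pi = k / analyzed_sites` holds exactly;
* **a single-copy MHC exon** — diploid sequence locus;
* **a possibly-duplicated MHC locus** — 1–4 distinct alleles per individual
  with no copy-number information.  Allele frequencies use the
  uncertain-copy-number rule: a single-allele individual contributes two
  counts of its allele, a multi-allele individual one count per distinct
  allele.  This underestimates common-allele and overestimates rare-allele
  frequencies, which is why the pipeline also carries the frequency-free
  APD statistic and reports the multicopy Ewens–Watterson test with an
  explicit `multicopy` flag.

Half-locus calls contribute their single scored allele once and reduce the
gene-copy total by one.  This keeps frequency estimates unbiased when
dropout is random with respect to allele identity; the choice is a design
decision (the alternative — discarding half-locus calls — wastes data and
is biased under allele-size-dependent dropout).

## Statistics implemented

**Diversity.** Allelic richness `A` with hypergeometric rarefaction
`A_g = sum_i [1 - C(n - n_i, g) / C(n, g)]` (the expected allele count in a
subsample of `g` gene copies; `A_n = A` and `A_1 = 1` exactly); plain and
`n/(n-1)`-unbiased expected heterozygosity; segregating sites `S`, mean
pairwise differences `k`, haplotype diversity `H_D = n/(n-1)(1 - sum p_h^2)`
and nucleotide diversity `pi`, with Nei's sampling variances for `H_D` and
`pi` and an optional bootstrap-over-individuals SD.  The **APD** (average
percent difference) between individuals uses the Dice similarity on allele
multisets, `S_xy = 2 n_xy / (n_x + n_y)`; APD is the mean of
`100 (1 - S_xy)` over all `N(N-1)/2` pairs.  Dice was chosen because it
makes APD and the differentiation analog F' share one similarity kernel,
which is exactly the relationship the two statistics are meant to have.

**Differentiation.** Weir–Cockerham variance components give per-locus and
multilocus theta with a bootstrap-over-loci CI and permutation p-values
(permutation unit: the individual, both gene copies together — conservative
under within-individual correlation).  AMOVA Phi_ST uses Kimura
two-parameter distances between haplotypes treated as squared distances
(the convention of the standard AMOVA implementations); with the 0/1
identity distance the same machinery returns the conventional
haplotype-frequency F_ST, and the two are verified to agree with a direct
spectrum-based computation.  Jost's D_est uses nearly unbiased
heterozygosity estimators with gene copies as the sampling unit
(`Hs = (ntilde/(ntilde-1))(1 - mean sum p^2)`, harmonic-mean `ntilde`;
`Ht = 1 - sum pbar^2 + Hs/(ntilde k)`); simulation under panmixia confirms
the estimator is centred at zero at the sample sizes used here.  The
multilocus D_est is the harmonic mean over loci; because the harmonic mean
is undefined for non-positive values, those are floored at 1e-6 *inside the
mean only* and flagged, with raw per-locus values always reported.
`F' = (Sw - Sb)/(1 - Sb)` from mean within- vs between-population Dice
similarities, with two SEs: a delta-method propagation treating pairs as
independent, and a jackknife over individuals.  The exact variance of the
original Taylor-expansion formulation is not recoverable from the
literature the statistic comes from, so both generic estimates are emitted
and labelled.  The exact test of allele-frequency differentiation is a
Metropolis walk over contingency tables with fixed margins; on 2x2 tables
it reproduces Fisher's exact p to MC accuracy.

**Neutrality.** Tajima's `D = (k - S/a1)/sqrt(e1 S + e2 S(S-1))`; its
p-value conditions on the observed `S` (mutations placed multinomially on
coalescent branches by length, Arlequin-style) rather than on a fixed
theta — the two conventions differ in tail mass, and fixed-S is the one the
reported tables of this analysis family use.  Fu's
`F_S = ln(S'/(1 - S'))` with `S' = Pr(K' >= K | theta = k)` computed from
unsigned Stirling numbers of the first kind, evaluated entirely in log
space by the recurrence `|s(n+1,k)| = n|s(n,k)| + |s(n,k-1)|` (validated
against exact integer arithmetic for n <= 8); its p-value uses Fu's
lower-tail convention.  The Ewens–Watterson–Slatkin test compares observed
homozygosity `F_obs = sum (n_i/n)^2` with its expectation conditional on
`(n, K)`.  Conditional configurations are sampled by Chinese-restaurant
draws retained when the allele number matches: the conditional law is
theta-free, so the proposal theta (chosen to make `K` modal) affects only
efficiency, and the number of new tables is decided by the first-stage
Bernoulli draws alone, which makes rejection cheap.  This rejection sampler
targets the same distribution as a full MCMC over configurations and is
exact.  Reported tails: `P_H = Pr(F <= F_obs)` (the balancing-selection
direction — observed homozygosity lower than expected), the upper tail, and
the exact-style `P_E` (probability of configurations no more probable than
the observed one); reports label which is which because published tables
often print a single unlabelled p.

**Mismatch demography.** The sudden-expansion law implemented here is the
exact pair-coalescent distribution for a population whose mutation-scaled
size shifts from `theta0` to `theta1` at scaled time `tau`: conditioning on
whether a pair coalesces before or after the shift gives

```
F_j = Fhat_j(theta1) Pr(Pois(lambda tau) > j)
      + exp(-tau/theta1) sum_{i<=j} dpois(i, tau) Fhat_{j-i}(theta0)
```

with `lambda = (theta1+1)/theta1` and `Fhat_j(theta)` the equilibrium
geometric law.  This reduces to the classical printed approximation for
large `theta1`, and satisfies the three analytic limits exactly (geometric
at `tau = 0` or `theta1 = theta0`; normalization; Poisson(`tau`) for
`theta0 = 0`, `theta1 -> inf`).  Fitting is least squares over classes up
to the largest observed difference (so zero-padding the tail cannot change
the fit), with `theta1` parameterized as `theta0 + delta >= theta0`, a cap
of 1e5, 27 grid starts with Nelder-Mead and best-start fallbacks, and ties
broken toward the smallest `tau`.  SSD and Harpending's raggedness
(`r = sum (x_i - x_{i-1})^2` with zero classes padded on *both* ends, so
the initial rise and final fall both count) get p-values from a parametric
bootstrap that refits every simulated replicate — both statistics use the
expansion-model bootstrap, a documented choice since the alternative (a
stationarity null for raggedness) is equally defensible.  Because the
p-value only compares the observed statistic with refitted simulated ones,
its calibration requires the same fitting budget on both sides; the
calibration suite uses matched reduced budgets for exactly this reason.
The test's power against stationary data is real but modest (about 20-30%
at n = 40, theta = 10 in our experiments), consistent with what is known
about mismatch goodness-of-fit statistics; the test suite asserts the
directional property rather than a high power figure.

**Genotype QC.** The comparative multi-tubes consensus rule: a heterozygote
needs each allele seen in >= 2 PCRs, a homozygote three concordant
homozygous PCRs; conflicts consume further replicates (at most 7) until
every reported allele is seen twice, else the call degrades to half-locus
or missing — an allele seen once is never reported.  If exactly two alleles
are confirmed alongside a third singleton, the confirmed pair is reported
(tie-break design decision).  Error rates from paired
reference/test genotypes define allelic dropout on
reference-heterozygous comparisons only (a homozygote cannot drop to a
different genotype), false alleles as test alleles absent from the
reference, and total error per allele slot (two per genotype) — the
denominator choice is documented because published totals rarely state it.
Null-allele EM follows the classical expectation-maximization estimator
(apparent homozygotes apportioned between true and null-carrying
genotypes), treats blanks as null homozygotes only on request, and polishes
the boundary: EM approaches `r = 0` only sublinearly, so if the plain-HW
boundary model is at least as likely as the converged interior point the
MLE is reported as 0.  Exact HWE uses the Levene conditional distribution
with Monte-Carlo pairings of gene copies; genotypic LD uses the G statistic
with genotype-permutation nulls.

**Group comparisons.** Kruskal–Wallis H (tie-corrected) with a
randomization p (exhaustive enumeration for small two-group cases),
Levene's test on absolute residuals from group means, the rank-sum Z test
with tie and continuity corrections (exact enumeration when both groups
have <= 10 observations), Pearson chi-square contingency tests, and Holm's
sequential Bonferroni correction.  The published description of the
two-population comparison names a sign-rank test in an unpaired setting;
the unpaired rank-sum Z is what the data admit, and the discrepancy is
noted here rather than silently resolved.  For APD comparisons the unit of
observation is the pair-level percent difference; pairs share individuals,
so the reported randomization p should be read as approximate — both this
and the test statistics themselves are emitted so the reader can judge.

## The synthetic two-population generator

The generator emulates the study design, not any particular dataset: two
populations of ~30–36 genotyped individuals; 13 microsatellites from a
finite-island forward Wright–Fisher model with stepwise mutation (burn-in
10 N_e generations from a monomorphic start); neutral sequence loci from a
two-deme structured coalescent with infinite-sites mutation (time scaled in
1/(2u) units, per-pair coalescence at rate 1/theta, mutation at 1/2 per
lineage, migration at M/(2 theta) per lineage with M = 4 N_e m), with the
intron carrying two indel events totalling 14 bp; an MHC-like exon from
forward-time multiallelic symmetric overdominance (fitness 1 for
heterozygotes, 1 - s for homozygotes; selection has no simple coalescent,
which is why this locus is simulated forward); and a multicopy locus built
by pooling the four gene copies of two underlying diploid loci and dropping
each copy independently with a detection-dropout probability.  The `skewed`
selection mode pins one focal allele at a target census frequency in one
deme only (default 0.44, the predominant-allele pattern the design
emulates) while overdominance keeps the remaining alleles even — an
explicitly phenomenological stand-in for spatially heterogeneous selection,
with no mechanistic claim.  Replicate-PCR error applies per-PCR allelic
dropout per heterozygote allele and false-allele substitution.

Infinite-sites placement means `S` equals the mutation count, which keeps
the test oracles simple; recurrent mutation, recombination and linked
selection are deliberately not modelled.  Passing tests on this generator
therefore demonstrate correctness of the statistics and the qualitative
selection signatures, not robustness to homoplasy or linkage, and say
nothing about chromatogram-level allele calling.

Default parameter choices and why: `theta` of 1.0 (intron), 2.3 (MHC exon)
and 8 (multicopy halves) reproduce the observed ordering of sequence
diversity across marker classes at desk-scale sample sizes; `s = 0.3` is a
calibration choice, not an estimate — the literature this design follows
reports no quantitative selection strength; `N_e = 500` (default) with
`m = 0.002` gives the low-but-significant neutral differentiation regime
the contrast needs; per-PCR dropout 0.05 and false-allele 0.01 produce
consensus-level error below 1%, matching the reported behaviour of
comparative multi-tubes protocols.  Directional and calibration test
studies run at reduced deme sizes (N_e = 60–300) and generations (a few
thousand), stated in each test; these sizes keep overdominance strong
(N_e s >= 90) while staying at desk scale.

## Numerical choices

* Stirling numbers, Ewens probabilities and Fu's tail sums are computed in
  log space with log-sum-exp; the Stirling triangle is cached per `n`.
* Rarefaction uses `exp(lchoose(...))`, stable for hundreds of copies.
* K2P saturation (log argument <= 0) returns `Inf` and is flagged; the
  AMOVA replaces non-finite distances by the largest finite one with a
  warning.
* The coalescent floors `theta` at 1e-8 so a zero-size epoch degenerates to
  instantaneous coalescence instead of an infinite-rate error.
* Monte-Carlo p-values use inclusive comparisons (`<=` / `>=` with a 1e-12
  slack), making them conservative at ties.
* Master seed -> per-stage seeds via a fixed affine counter scheme
  (mod 2^31 - 1), so any stage can be re-run independently and the full
  pipeline is bit-reproducible.

## Known limitations

* The multicopy locus's sequence-level statistics are computed on the
  estimated allele counts of the counting rule and are approximations;
  rows carry a `multicopy` flag.
* F' standard errors are generic (delta method, jackknife), not the
  original Taylor-expansion variance.
* The mismatch SSD/raggedness bootstrap is approximately calibrated (the
  usual parametric-bootstrap caveat) and weak against stationarity at
  moderate theta.
* With migration rate zero the two-deme coalescent has no common ancestor;
  the sequence simulator therefore requires M > 0 (the forward-time
  microsatellite model accepts m = 0, where loci may fix).
* Problem sizes in the test suite (deme sizes 60–300, 500-replicate
  calibration studies, reduced inner Monte-Carlo budgets) are the package's
  chosen desk-scale study conditions; all are stated where used.
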
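Package: mhccontrast
Title: Contrasting Neutral and MHC Genetic Variation in Paired Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for contrasting patterns of genetic variation
    at putatively neutral markers (microsatellites, a nuclear intron) with
    MHC loci in two populations: within-population diversity (allelic
    richness with rarefaction, heterozygosity, sequence diversity, average
    percent difference), between-population differentiation (Weir-Cockerham
    F_ST, AMOVA Phi_ST with Kimura two-parameter distances, Jost's D_est,
    the similarity-based F', exact tests), neutrality tests (Tajima's D,
    Fu's F_S, the Ewens-Watterson-Slatkin homozygosity test), mismatch
    distributions with sudden-expansion fitting, replicate-PCR consensus
    genotyping with error-rate and null-allele estimation, and a synthetic
    two-population generator (coalescent and forward-time, with a fecal-DNA
    genotyping error model) so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
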
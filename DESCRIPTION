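Package: sweepscan
Title: Selection Scans, Archaic Introgression and Phenotype Association on Phased Haplotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed selection scans on phased diploid haplotype panels using the
    population branch statistic (PBS), cross-population extended haplotype
    homozygosity (XP-EHH) and a rank-based Fisher score, with percentile
    thresholding, interval merging and resampling significance; per-region
    candidate-SNP ranking by a Wright-Fisher allele-frequency-trajectory
    likelihood ratio; archaic-introgression tract detection with a two-state
    Poisson hidden Markov model, ancestry assignment and linkage-based haplotype
    clustering; linear-mixed-model phenotype association with kinship correction
    and Benjamini-Hochberg calling; and summary-statistic lookup with a
    resampling blood-phenotype enrichment test. Ships a seeded synthetic-data
    generator (Balding-Nichols differentiation over a founder-mosaic haplotype
    backbone, injectable sweeps, archaic tracts and SNP-effect phenotypes) so the
    whole pipeline is testable end to end without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
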
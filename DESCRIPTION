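Package: frostphage
Title: Heavy-Water SIP Viromics: Simulation and Inference for Active
    Viruses and Hosts in Sub-Freezing Soils
Version: 0.1.0
Authors@R:
    person("Jordan", "Winter", email = "jwinter@example.org",
           role = c("aut", "cre"))
Description: Simulates H2-18O stable isotope probing (SIP) metagenomics of
    a soil virus-host community (isotope labeling of newly synthesized DNA,
    CsCl buoyant-density banding, density-fraction binning and short-read
    sampling) and implements the downstream inference used in SIP viromics:
    viral population (vOTU) clustering at 95% average nucleotide identity
    over 85% of the shorter contig, coverage-based presence calling
    (>=90% read identity, >=75% breadth), the 18O-presence/16O-absence
    activity rule for vOTUs, read-subtraction and zero-inflated log-normal
    fold-change activity calls for genome bins (MAGs), CRISPR-spacer and
    shared-content virus-host linkage with provirus and temperate-phage
    classification, the activity-by-linkage cross-tabulation, and diversity,
    trajectory and virus:host regression statistics. A seeded synthetic
    community generator provides ground truth so every stage can be scored
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
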
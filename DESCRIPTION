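Package: tetramap
Title: Linkage Maps, Half-Tetrad Centromere Mapping and QTL Scans for
    Salmonid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for genetic linkage mapping in
    species with strong heterochiasmy (salmonid-style telomere-restricted male
    recombination). Provides a meiosis and half-tetrad simulator with known
    truth, marker quality control including a LOD-position-matrix filter,
    two-point LOD linkage grouping with iterative threshold splitting, marker
    ordering by sum of adjacent recombination fractions, sex-specific map
    construction, centromere localization from gynogenetic half-tetrad
    offspring heterozygosity (y) profiles and maternal recombination-fraction
    (RFm) profiles, single-QTL genome scans for normal and binary traits with
    permutation significance, Bayes credible intervals and proportion of
    variance explained, chromosome-specific recombination-rate estimation by
    resampled pairwise regression, and classification of chromosomal
    inversions as pericentric or paracentric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
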
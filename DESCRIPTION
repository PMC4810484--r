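Package: steromine
Title: Genome Mining for Aerobic Steroid-Degrading Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested re-implementation of a comparative-genomics pipeline for
    delineating bacteria encoding the aerobic 9,10-seco steroid degradation
    pathway: reference-protein binning by thresholded sequence similarity,
    reciprocal-best-hit orthology, profile hidden Markov model screening of
    proteomes, a presence/absence degrader classification rule over eight key
    enzyme groups, detection of steroid catabolism gene clusters on chromosomes
    and plasmids, and multilocus phylogenetic congruence analysis against a
    16S-like species tree. Includes a seeded synthetic-genome simulator with
    planted pathway gene clusters and optional horizontal gene transfer, used
    to exercise and validate every stage end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
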
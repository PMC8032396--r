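Package: haplodiv
Title: Temporal Haplotype Diversity of Ancient and Modern Mitochondrial Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing mitochondrial genetic diversity between time-stratified
    cohorts, built around aligned control-region or mitogenome sequences with ancient and
    modern strata. Collapses alignments into haplotypes under explicit missing-data
    policies, estimates haplotype diversity (Nei's unbiased estimator), segregating sites
    and nucleotide diversity with pairwise deletion, places an ancient cohort's diversity
    within a bootstrap-rarefaction null distribution drawn from the modern cohort at the
    ancient sample size, builds minimum-spanning and two-layer temporal haplotype
    networks with shared/private haplotype accounting, and discriminates two
    osteometric size groups with permutation tests. Includes a synthetic-data generator
    emulating a haplotype pool with configurable maternal lineage loss and ancient-DNA
    style damage (terminal C-to-T / G-to-A artifacts, missing data), so the whole
    pipeline is testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    MASS,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
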
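Package: bsares
Title: Genomic Resolution of Bulk Segregant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the expected genomic mapping resolution of bulk
    segregant analysis (BSA) experiments from coalescence theory, via a
    lineage-count recursion together with closed-form approximations, and
    validates the predictions with a forward Wright-Fisher simulator that
    tracks ancestry junctions along chromosomes. Also provides the marker
    layer used in practice: pool genotyping at marker grids, Pool-seq
    coverage resampling, the G statistic and its tricube-smoothed version
    G', and significance-peak calling. Supports the standard BSA crossing
    design as well as introgression-mapping and heterozygote-selection
    schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
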
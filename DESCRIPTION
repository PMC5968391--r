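Package: rdhfp
Title: Reductive Dehalogenase Gene Fingerprinting and Strain Inference for
    Dechlorinating Communities
Version: 0.1.0
Authors@R:
    person("KB", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for resolving Dehalococcoides mccartyi strains in mixed
    dechlorinating cultures and groundwater from reductive dehalogenase
    (rdhA) gene data. Classifies RdhA sequences into ortholog groups at a
    pairwise-identity threshold, builds neighbor-joining trees with midpoint
    rooting, screens qPCR primers in silico, fits qPCR standard curves and
    converts quantification cycles to absolute gene copies with method
    detection limits, forms rdhA/16S rRNA gene-copy ratio fingerprints with
    censoring, clusters fingerprints by Pearson correlation and UPGMA, and
    infers the minimum number of co-existing strains by decomposing ratio
    vectors into binary gene-content mixtures. Includes a synthetic
    community and qPCR plate simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
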
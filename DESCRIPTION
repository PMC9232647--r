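Package: haplomt
Title: Mitochondrial Haplogroup Discovery, Dating and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the inference workflow behind mitochondrial DNA (mtDNA)
    haplogroup discovery: parsing and applying PhyloTree-style variant
    nomenclature, haplogroup classification against a reference tree with a
    definitive-placement rule, strict-clock Bayesian divergence dating under a
    partitioned HKY+Gamma model with a Bayesian-skyline coalescent demography,
    maximum clade credibility summarisation, parsimony and maximum-likelihood
    ancestral-state reconstruction with per-branch synapomorphy extraction,
    population-label ancestral reconstruction, haplogroup frequency
    aggregation, and a coalescent simulator that generates every fixture the
    pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    yaml
Config/testthat/edition: 3
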
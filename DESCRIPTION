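Package: invclinal
Title: Inversion and Polygenic Contributions to Trait Divergence in Contact Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics tools for hybrid zones between locally
    adapted ecotypes. Calls chromosomal inversion karyotypes from SNP data by
    principal-component clustering, builds inversion-free genomic relationship
    matrices (Yang et al. estimator) with a centimorgan buffer around inversion
    regions, and fits animal models by restricted maximum likelihood with
    inversion, sex and environmental fixed effects to partition phenotypic
    variance into inversion, polygenic and environmental components. Includes
    conditional Wald tests with false-discovery-rate correction, likelihood-ratio
    tests for additive genetic variance, spatial relatedness profiles along a
    sampling transect, and a forward simulator of clinal contact zones with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
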
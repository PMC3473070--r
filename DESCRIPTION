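Package: arraycall
Title: Single-Array SNP Genotyping with Semi-Parametric Log-Concave Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calls genotypes for all SNPs on a single microarray at once.
    Two-channel allele intensities are transformed to (strength, contrast)
    coordinates, binned on a two-dimensional histogram, and a three-component
    mixture of smooth log-concave densities is fitted by EM.  Each component
    is a penalized Poisson tensor-product B-spline density (P-splines with a
    third-order difference penalty) fitted with a fast generalized linear
    array model (GLAM) solver, so runtime is almost independent of the number
    of SNPs.  Each SNP is assigned the genotype with the largest membership
    probability of its histogram bin.  Includes a synthetic-array simulator
    with Affymetrix-like and Illumina-like cluster geometries, concordance
    cross-tabulation, minor-allele-frequency and calling-quality summaries,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    splines,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
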
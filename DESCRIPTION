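Package: quantpar
Title: Parentage Assignment and Pooled-Sample Analysis from Quantitative SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for parentage assignment and pooled-DNA analysis from
    low-density SNP assays that report raw two-channel intensities. Converts
    allele area measurements to allelic proportions by a polar-coordinate
    transform, calibrates per-SNP genotype cluster parameters, and represents
    each genotype as a quantitative 2x2 probability matrix rather than a
    discrete call. Matrix-formulated trio and pair likelihoods yield LOD
    scores for maximum-likelihood parentage assignment (quantitative,
    error-perturbed, and exclusion variants), and a stochastic greedy search
    reconstructs full-sib and half-sib pedigrees under mating constraints.
    The same quantitative framework estimates allele frequencies in pooled
    DNA samples and deconvolves per-family contributions to pools by
    weighted non-negative least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse
Config/testthat/edition: 3
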
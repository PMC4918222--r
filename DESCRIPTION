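Package: micat
Title: Mutual-Information Region Tests for Categorical Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Region-based association tests between multi-site genotypes
    (rare and common variants) and a nominal categorical trait. Implements
    the mutual-information test (MIT) and its symmetrized variant (aMIT)
    over the pseudocounted distribution of minor-allele counts across sites,
    with permutation inference; the baseline-category-logit score test as a
    parametric comparator; a latent-Gaussian genotype simulator with AR(1)
    linkage-disequilibrium structure and a registry of benchmark scenarios;
    and a Monte-Carlo harness for estimating empirical type-I error and
    power. Genotypes are read from plain TSV matrices or VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
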
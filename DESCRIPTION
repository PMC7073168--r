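Package: hrmpca
Title: High-Resolution Melting Curve Genotyping with PCA and
    Model-Based Clustering
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-nucleotide polymorphism (SNP) genotyping from
    high-resolution melting (HRM) curves. Provides readers and writers for
    plate-export melt tables, a two-state duplex melting simulator with
    known genotype truth, melt-region clipping and curve normalization,
    difference plots, principal-component embedding of melt curves,
    Gaussian-mixture clustering with Sanger-anchor genotype labelling,
    contingency chi-square marker-trait association, and EM estimation of
    haplotype frequencies from unphased multilocus genotypes. Ships the
    melt-region and genotype reference tables of a 27-cultivar peach
    chilling-requirement SNP marker panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
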
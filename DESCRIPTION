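Package: fawpopgen
Title: Host-Strain Genomic Differentiation and Sweep Scans for the Fall
    Armyworm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genomic analysis of host-plant strain divergence in
    the fall armyworm (Spodoptera frugiperda) and similar partially isolated
    population pairs. Implements windowed Weir-Cockerham F_ST and absolute
    divergence (D_XY) with genome-wide and per-window permutation tests, a
    genomic-differentiation classifier, genotype PCA and least-squares
    ancestry coefficients for hybrid detection, a site-frequency-spectrum
    composite-likelihood-ratio sweep scan with group-specific outlier
    calling, nuclear (TPI-like) and mitochondrial (COX1-like) strain
    assignment via locus PCA and F84 distances with neighbor joining, and a
    forward Wright-Fisher two-population simulator (migration, divergent
    selection, recombination, rescaling) used to validate the F_ST/D_XY
    signature of divergent selection under reduced gene flow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
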
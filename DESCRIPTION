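Package: sexdimorph
Title: Sex-Biased Expression Analysis for Monosex Fish Embryos
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of sexually differentially expressed genes and
    microRNAs in early fish embryos of known gender (all-male or all-female
    broods). Implements two-color microarray normalization (within-array
    loess on the M-A representation, between-array quantile normalization of
    average intensities) followed by a per-probe fixed-effects linear model
    with least-squares gender means, an empirical rank-based false discovery
    rate and a Poisson family-wise correction; a z-deviation test for
    sex-biased small-RNA expression with an empirical tail FDR; a
    miRNA-target concordance sign test; absolute qPCR quantification with
    standard curves, reference-gene normalization and copy-number ratios;
    deletion detection between paralogous coding sequences with frameshift
    consequence prediction; and marker-sex concordance for linkage
    assignment. Every stage can be exercised on synthetic data produced by
    the bundled generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
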
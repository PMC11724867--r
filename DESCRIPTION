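Package: fanolattice
Title: Finite-Sample Lattice Patterns in Mean-Fano Factor Plots of
    Single-Cell Transcript Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the deterministic patterns that finite
    sample size imprints on mean-Fano factor plots of single-cell
    transcript count matrices. Computes per-gene moments in exact
    rational arithmetic, predicts the family of curves traced out by
    genes with k cells at two transcripts and the discrete lattice of
    attainable (mean, Fano factor) points at i/n_c, quantifies the
    1/n_c quantization of vertical spacings between neighbouring genes
    on a curve, and matches observed genes to the predicted lattice.
    Includes readers and writers for Matrix Market (10x-style) and
    dense CSV/TSV count matrices, a synthetic count-matrix generator
    (Bernoulli, Poisson, negative binomial, telegraph, arbitrary
    discrete distributions, binomial capture thinning, extrinsic
    noise), ggplot2 visualisations, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    methods,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
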
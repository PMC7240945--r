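Package: leafflux
Title: Instationary 15N Flux Analysis and Amino Acid Fingerprints for Leaf Labeling Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing short-term 15N leaf-disc labeling experiments
    in plants. Corrects raw isotopologue mass fractions for natural isotope
    abundance and tracer impurity, represents precursor label-input curves
    analytically, estimates biosynthesis fluxes of single-nitrogen amino acid
    subsystems (two-reaction models at metabolic pseudo steady-state) by
    weighted least squares with chi-square goodness-of-fit verification, and
    reproduces amino-acid fingerprint statistics (abundance filtering,
    normality screening, PCA with correlation loadings, one-way ANOVA with
    Tukey HSD letters). Ships a seeded synthetic-data generator emulating a
    four-leaf-rank glycine labeling design so the whole pipeline is testable
    end to end with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
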
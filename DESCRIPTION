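Package: polarscope
Title: Proteomic Classification and Label-Free Motility Analysis of
    Polarized Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing cultured macrophage polarization
    states (M0, M1, M2a, M2c) from two complementary readouts. The
    proteomics arm processes TMT-style protein abundance matrices:
    total-abundance normalization, control-referenced log2 fold changes,
    median centering, per-subtype aggregation, threshold classification
    into differential and core proteomes, surfaceome filtering against a
    cell-surface protein atlas, Venn overlap summaries, hierarchical leaf
    ordering and PCA. The imaging arm quantifies spontaneous motility from
    label-free phase-contrast time-lapse stacks: translation drift
    correction, local-variance foreground detection, difference-of-Gaussian
    landscapes, extended-minima markers, area-restricted marker-controlled
    watershed, size-based cell/cluster classification, Jaqaman-style
    centroid tracking and per-track / per-field motion statistics.
    Synthetic generators with stored ground truth make both arms testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
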
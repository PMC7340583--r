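Package: wallquant
Title: Quantification of Cell-Wall Protein Fluorescence, Ligand Binding,
    and Mating Efficiency in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reference-strain-normalized pipeline for quantifying
    mCherry-tagged cell-wall protein levels in budding yeast from
    three-channel fluorescence Z-stacks (sum projection, cytosol-marker
    cell segmentation, cell-wall ring segmentation, per-cell intensity
    accounting, and tester-versus-reference Mann-Whitney comparison),
    together with one-site saturation radioligand binding analysis
    (Kd and Bmax estimation by nonlinear least squares) and quantitative
    mating-efficiency statistics (Welch t comparisons of replicate colony
    counts). A synthetic-scene generator with voxel-level ground truth
    makes every stage testable without microscope or scintillation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
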
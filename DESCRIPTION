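Package: smdyn
Title: Single-Molecule Fluorescence and Binding Thermodynamics Analysis of
    Protein Conformational Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising minor conformational states of
    intrinsically disordered proteins in their bound complexes, combining
    single-molecule multiparameter fluorescence detection (MFD) with
    isothermal titration calorimetry.  Simulates photon streams of freely
    diffusing labelled molecules with k-state conformational exchange,
    performs burst search and burst-wise/time-window FRET and anisotropy
    observables, fits shot-noise-limited probability distribution analysis
    (PDA) models globally across time windows, computes species-filtered
    fluorescence correlation (sACF/sCCF) with multi-component relaxation
    fits, evaluates static FRET lines and Perrin rotational-correlation
    analysis, predicts inter-dye distances from coarse-grained accessible
    volume simulations with Shrake-Rupley solvent accessibility, and
    dissects ITC titration series into binding thermodynamics including
    heat-capacity changes and Spolar-Record residues-folded estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    pracma,
    bio3d,
    yaml,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
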
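Package: aptafret
Title: Design and Quantification Pipeline for RNA Aptamer-Based FRET on
    Single-Stranded RNA Origami Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building FRET systems from fluorogenic RNA aptamers
    (Spinach/Broccoli with DFHBI-1T, Mango with YO3-biotin) positioned on
    two-helix antiparallel-even (2H-AE) single-stranded RNA origami tiles.
    Compiles 2D blueprints into a single-strand trace, pseudoknot-aware
    dot-bracket structure and sequence-design constraints (G-C crossover
    locks, periodic GU wobbles, T7 initiation sequence); models the tile as
    parallel A-form helices to predict inter-fluorophore distance, dipole
    orientation factors and transfer efficiency; implements ratiometric
    FRET quantification with spectral corrections for cuvette,
    flow-cytometry and single-cell confocal data, including dose-response
    (EC50) fitting, spectral-overlap integrals, cell segmentation and
    Gaussian-mixture analysis of per-cell FRET histograms; and provides
    seeded synthetic-data generators with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    jsonlite,
    mclust,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
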
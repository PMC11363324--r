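Package: aquabridge
Title: Water-Mediated Ligand Engagement, Proximity Proteomics, and
    Opioid Pharmacology Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for structural and pharmacological
    characterization of bitopic opioid-receptor ligands. Classifies
    simulation frames by how a ligand hydroxyl engages the sodium-site
    aspartate (directly, through one or two bridging waters, or not at
    all), scores pi-pi stacking and hydrogen-bond frequencies across
    replicate trajectories with Mann-Whitney comparisons, deconvolves
    APEX proximity-labeling intensities into subcellular location
    coefficients and calls time-course hits with polynomial F-tests,
    and fits four-parameter logistic concentration-response and
    log-logistic dose-response (ED50) models. Includes seeded
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
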
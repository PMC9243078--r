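Package: adhescreen
Title: Genome-Wide siRNA Adhesion-Screen Analysis for Bacterial Binding Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content siRNA screens that identify
    host-cell receptors for adherent bacteria. Provides a synthetic screen
    generator (siRNA library manifests, 384-well plate layouts with control
    wells, latent adhesion-effect model, per-well counts and rendered
    two-channel well images), two-channel image quantification (background
    correction, Otsu thresholding, nuclei as main objects and bacterial
    puncta as subobjects, bacteria-to-nuclei ratio), per-plate control-based
    quality control, percent-of-negative-control and antibody-block
    normalization, the three-round hit-calling cascade with replicate-siRNA
    concordance rules, and percent-adhesion statistics for antibody-blocking
    validation assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
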
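Package: coarckit
Title: Synthetic Aortic-Arch Morphometry and Reduced-Order Coarctation
    Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying aortic coarctation (CoA) across aortic arch
    morphologies. Generates parametric arch geometries (gothic, crenel and
    romanesque shape families) as analytic centerline-plus-radius phantoms and
    voxelized masks; implements CTA-style arch morphometry (level diameters
    AOA and D1-D5, height-to-width ratio A/T, AAO-DAO and TAO-DAO angles,
    arch classification, hypoplasia and coarctation criteria); reproduces
    cohort group statistics from raw measurements or from published
    (mean, SEM, n) summaries; and solves a reduced-order pulsatile
    one-dimensional arterial network with a Young-Tsai-type stenosis
    pressure-loss element, including calibration of stenosis severity against
    a Doppler-style simplified-Bernoulli pressure gradient.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    igraph,
    jsonlite,
    yaml,
    RNifti,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
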
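Package: mrartefact
Title: Simulation and Automated Detection of Motion Artefacts in MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Synthesizes magnetic resonance (MR) motion artefacts by corrupting
    k-space data according to bulk rigid-body or respiratory motion trajectories
    under Cartesian, radial, or spiral sampling, and detects artefact-corrupted
    images with a decision forest trained on box, line, histogram, and Haralick
    texture features under subject-disjoint nested cross-validation. Includes
    seeded brain-like and cardiac-like phantom generators so the full pipeline
    runs without external data, a Kaiser-Bessel gridding implementation of the
    non-uniform discrete Fourier transform for radial and spiral trajectories,
    and a command-line interface for phantom generation, artefact simulation,
    and detection experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    png,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
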
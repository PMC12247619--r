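Package: linescanr
Title: Simulation and Depth-Resolved Analysis of Laminar Line-Scanning fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for laminar line-scanning functional MRI in small animals:
    closed-form steady-state signal models for spin-echo (alpha-180) and
    gradient-echo line-scanning sequences with analytic flip-angle
    optimization and relative temporal-SNR prediction; a block-design
    gamma-variate hemodynamic response model with GLM amplitude estimation;
    a seeded generator of depth-by-time line-scanning series and 2D
    line-profile images with known ground truth; the per-voxel conditioning
    chain (demeaning, polynomial detrending, zero-phase FIR bandpass with
    group-delay compensation, z-scoring, temporal SNR); and depth-resolved
    functional metrics (percent-change maps, epoch averaging, peak-layer
    detection, laminar slope, profile FWHM, background fraction). Series are
    exchanged as NIfTI-1 with JSON sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
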
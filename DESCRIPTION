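Package: planDVH
Title: Dose-Volume Histogram Analysis and Radiotherapy Plan Quality Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds differential, cumulative, spatial (per-slice) and surface
    dose-volume histograms from a contoured 3D dose grid; rasterizes planar
    structure contours to voxel masks with optional sub-voxel supersampling;
    extracts arbitrary DVH statistics (Dx, Vx, coverage at prescription-dose
    fractions) via cosine-interpolated piecewise-polynomial cDVH smoothing;
    scores treatment plans with a ten-index universal plan-index set and an
    exponential quality factor; and evaluates Poisson tumor-control and
    Lyman equivalent-uniform-dose normal-tissue-complication models.
    Includes a seeded synthetic phantom generator with closed-form DVH
    oracles, a plain-text plan-bundle exchange dialect, spreadsheet-style
    reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'planDVH-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'rasterize.R'
    'dvh.R'
    'smooth.R'
    'compare.R'
    'spatial.R'
    'indices.R'
    'radiobiology.R'
    'phantom.R'
    'plan-io.R'
    'report.R'
    'cli.R'
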
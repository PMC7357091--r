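Package: discmri
Title: Quantitative MRI of the Intervertebral Disc
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative lumbar
    intervertebral disc MRI. Provides a synthetic sagittal spine phantom
    with known per-disc ground truth (multi-echo spin-echo, single-echo
    T2-weighted and dual-echo complex Dixon acquisitions under Rician or
    complex Gaussian noise), voxelwise T2 mapping by log-linear least
    squares, two-point asymmetric-echo water/fat separation with
    field-map candidate enumeration, region growing and Gauss-Newton
    refinement, a five-subregion disc ROI model with central-slice
    metric extraction and nucleus/annulus normalization, interpolated
    disc surfaces, and the cohort statistical battery (group and grade
    contrasts by unpaired t-tests, Pearson correlation matrices,
    mean (SD) summary tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
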
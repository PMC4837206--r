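Package: ramanlayers
Title: Depth-Resolved Confocal Raman Analysis of Layered Vessel Walls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing confocal Raman Z-stacks of the vessel wall:
    reading and writing plain-text hyperspectral cubes, cosmic-ray removal,
    degree-2 polynomial baseline correction (plain and iteratively
    peak-clipped), region-restricted vector normalization, depth-wise layer
    assignment (endothelium vs media), marker-band integration (CH stretch at
    2940 1/cm, phenylalanine at 1007 1/cm), the lipid-to-protein ratio
    statistic, and control-versus-metastasis group comparison with
    mean +/- SEM and two-sample t tests.  A synthetic phantom generator
    renders layered vessel-wall Z-stacks with known ground truth so that
    every stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
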
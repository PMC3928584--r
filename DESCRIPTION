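Package: morphotree
Title: Branch-Level Morphometry of Digitally Reconstructed Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reads SWC digital reconstructions of neurons, partitions the
    traced segments into branches and their genealogy, orders branches
    topologically (Strahler and centrifugal), removes z-axis digitization
    noise with an arc-length moving-average filter, and computes per-branch
    morphometrics: length, tapering, distance-metric and sum-of-angles
    tortuosity, bifurcation angles and per-bifurcation Rall exponents.
    Populations of cells are summarized as Sturges-binned frequency
    distributions, and those empirical distributions can be resampled to
    grow non-identical virtual neurons emitted as valid SWC files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'swc-io.R'
    'topology.R'
    'morphometry.R'
    'branch-geometry.R'
    'fixtures.R'
    'statistics.R'
    'generator.R'
    'smoothing.R'
    'cli.R'
    'morphotree-package.R'
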
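Package: spatiodyn
Title: Quasi-Periodic Pattern Detection and Complex PCA for Parcellated BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and characterization of recurring spatiotemporal
    patterns in parcellated resting-state BOLD time series. Implements
    iterative sliding-window template matching for quasi-periodic patterns
    (QPPs), complex principal component analysis of the Hilbert analytic
    signal (phase-coherent modes, phase delay maps), infraslow band-limiting
    and global signal regression, TR decimation, network aggregation over a
    246-ROI / 9-network parcellation, event-set agreement metrics (modified
    Jaccard index with temporal cushion, precursor time-point analysis),
    nonparametric statistics, and a synthetic-data generator that plants
    quasi-periodic propagating patterns with known ground truth for recovery
    experiments and fidelity sweeps over scan length, TR and frequency band.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
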
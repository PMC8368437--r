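Package: ictalmeg
Title: Ictal MEG Source Imaging and Band-Limited Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of ictal magnetoencephalography (MEG)
    recordings of 3-Hz generalized spike-wave discharges, as seen in
    childhood absence epilepsy. Provides a synthetic multichannel MEG
    generator with known ground truth, amplitude-based artifact rejection,
    zero-phase decomposition into six canonical frequency bands (1-4 to
    80-250 Hz), automatic ictal-segment detection, current-dipole lead
    fields in a homogeneous conducting sphere, linearly constrained
    minimum-variance (LCMV) beamforming, accumulated source imaging (ASI),
    correlation-based source-space functional connectivity thresholded by
    the t-statistic of the correlation coefficient, and responder versus
    nonresponder group statistics (exact contingency-table tests with
    Bonferroni correction across bands, and clinical cohort summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
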
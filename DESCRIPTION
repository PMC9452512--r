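Package: bindclust
Title: Occupancy Models and Inference for Transcription-Factor Binding-Site Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanical occupancy models for clusters of
    transcription-factor binding sites, including overlapping sites with a
    steric clash energy; two-parameter saturation-binding-curve inference
    with MCMC credible intervals; occupancy calibration, cross points and
    AIC/BIC model selection; plate-reader response processing and a
    thresholded occupancy-to-expression model; and seeded synthetic-data
    generators emulating microfluidic (iMITOMI-style) binding assays and
    plate-reader induction experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
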
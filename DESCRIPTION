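Package: minisfit
Title: Quantal Analysis of Miniature Postsynaptic Potentials by
    Genetic-Algorithm Distribution Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the source distribution (amplitude by 10-90% rise
    time, and incidence rate) of miniature excitatory postsynaptic
    potentials (minis) from paired somatic voltage recordings of "noise
    with minis" and pharmacologically isolated "noise alone" epochs.
    Simulated minis drawn from a mixture of four rotated bivariate normal
    distributions are superimposed on the noise-alone recording and a
    genetic algorithm adjusts the 26-parameter source model until the
    amplitude and rise-time histograms of events detected in the
    simulated trace are statistically indistinguishable from those
    detected in the real recording. Includes passive membrane property
    estimation from brief current pulses, recording-quality indicators,
    histogram discrepancy scoring with combined-centile cutoffs and
    envelope deviations, Wilcoxon signed-rank acceptance tests, and
    downstream analyses of incidence rates, mean amplitude versus
    inverse capacitance charge regression, and averaged generic source
    distributions. A synthetic-data module generates fully specified
    recordings with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
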
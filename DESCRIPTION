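Package: driftmetrics
Title: Tuning Metrics and Inclusion-Criteria Analysis for Drifting-Grating
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of visual-cortex neurons responding to a
    drifting-grating protocol (eight directions by five temporal frequencies,
    plus blank sweeps), reduces per-trial dF/F traces to evoked summaries, and
    computes the standard tuning metrics of the field: preferred condition,
    direction selectivity index, global orientation selectivity index,
    octave-scale preferred temporal frequency, and the coefficient of
    variation of the preferred-condition response, both plainly and with
    split-half cross-validation.  Implements five published responsiveness
    inclusion criteria and the robustness analyses that quantify how those
    criteria reshape population tuning summaries: CV-ranked inclusion curves,
    decile distributions, Mann-Whitney comparisons, CV-matched selection, and
    trial-count sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    jsonlite,
    yaml,
    withr,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
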
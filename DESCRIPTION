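Package: circwave
Title: Waveform Analysis of Circadian Protein Turnover and Feedback Phases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing the waveforms of circadian protein abundance
    profiles. From a periodic protein time course the package computes the
    waveform-imposed lower bound R(t) on the degradation rate, the smallest
    compatible constant rate r_min and its hotspot, the biosynthetic cost of
    maintaining the waveform and the cost reduction achieved by rhythmic
    degradation. Given an mRNA profile and sparse measured degradation rates
    it reconstructs the full time-varying degradation-rate curve, with the
    capping, flooring and artifact-window corrections used for plant clock
    proteins, and an anchors-only estimator for the mammalian PER2 case. A
    second set of tools implements the two-component negative-feedback theory
    of the mammalian clock (active CLOCK-BMAL1 versus free PER-CRY): ODE
    simulation to the limit cycle, inhibitor waveform reconstruction,
    feasibility floors, closed-form and numeric peak-time differences, regime
    classification and a waveform-symmetry index. A synthetic-data generator
    produces fully specified ground-truth scenarios for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
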
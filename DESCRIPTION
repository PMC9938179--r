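Package: somnoscope
Title: NREM Sleep Oscillation Detection, Coupling and Single-Unit Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of the cardinal oscillations of
    non-REM sleep (cortical slow-waves, thalamocortical spindles, hippocampal
    ripples) from local field potential recordings, together with slow-wave to
    spindle phase-amplitude coupling (Tort modulation index), single-unit
    firing, bursting, event-locked and pairwise-correlation analyses, rule
    based vigilance-state scoring, baseline versus post-drug windowing and the
    accompanying group statistics. Includes a fully parameterised synthetic
    polysomnography generator (1/f background, state schedule, event
    injection, inhomogeneous-Poisson spike trains with common input) used for
    validating every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
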
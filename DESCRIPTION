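Package: rotodbs
Title: Rotometry Analysis of Deep Brain Stimulation Parameter Sweeps
Version: 0.1.0
Authors@R:
    person("rotodbs", "developers", email = "rotodbs@example.org",
           role = c("aut", "cre"))
Description: Tools for the systematic evaluation of deep brain stimulation
    (DBS) parameters through induced rotational behavior in the unilateral
    6-OHDA (hemi-parkinsonian) rat model. Provides a charge calculus for
    biphasic charge-balanced stimulus waveforms (rectangular, sinusoidal,
    triangular and linearly decaying envelopes), builders for
    amplitude / frequency / waveform-charge session protocols, a
    phenomenological synthetic cohort simulator producing angular and
    positional trajectories, per-episode rotometry feature extraction
    (maximum and net rotation, area under the rotation curve, path length),
    Euclidean-distance similarity matrices between condition trajectories,
    and the small-n inference layer (Pearson correlation with exact
    two-tailed significance, paired waveform t-tests). A command-line
    interface ties the stages into reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
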
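Package: tebcosc
Title: Hippocampal Oscillation Dynamics During Trace Eyeblink Conditioning
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of rat hippocampal local field potentials
    (LFP) and eyelid EMG recorded during trace eyeblink conditioning (TEBC):
    conditioned-response scoring and learning curves, artifact handling,
    Laplacian (CSD) re-referencing, a log-spaced zero-phase FIR filter bank
    with Hilbert analytic signals, time-frequency amplitude and intertrial
    coherence, interareal phase synchronization with trial-shuffle
    normalization, n:m phase-amplitude coupling, differential phase transfer
    entropy, and the surrogate/permutation statistics that go with them
    (sign-flip Monte Carlo, Benjamini-Hochberg FDR, cluster-based permutation,
    repeated-measures ANOVA). Ships a synthetic TEBC session generator with
    known ground truth so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
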
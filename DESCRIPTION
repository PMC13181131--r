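Package: seqssvep
Title: Analysis of Sequential-Flicker Steady-State Visual Evoked Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying whether spatially organized sequential visual
    flicker enhances high-frequency (100-190 Hz) local field potential power
    in visual cortex. Provides frame-accurate construction of sequential
    flicker stimulus schedules and their timing-derived quantities (repeat
    frequency, section phase shift, visual angles); a synthetic
    Neuropixels-like recording generator with ground-truth SSVEP entrainment,
    injectable high-frequency power, spike phase locking, waveform classes
    and receptive fields; an LFP spectral chain (Butterworth filtering and
    downsampling, trial-averaged evoked responses, Welch power spectra, the
    discrete Stockwell transform, normalized evoked-contrast spectra, and
    high-frequency amplitude and spatial-size metrics); single/multi-unit
    analysis (MUA extraction, waveform classification, responsiveness
    gating, spike-triggered-average receptive fields, pairwise phase
    consistency); paired statistics (exact Wilcoxon signed-rank, two-way
    repeated-measures ANOVA with Bonferroni post-hocs); and a workflow
    runner producing machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
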
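Package: bandalff
Title: Frequency-Band-Specific ALFF/fALFF Analysis of Resting-State BOLD Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the amplitude of low-frequency fluctuations (ALFF) and
    fractional ALFF (fALFF) of resting-state BOLD fMRI time series in the
    canonical slow-6 to slow-2 frequency bands, with the group-level machinery
    used in band-specific resting-state studies: voxelwise 2x2 mixed-design
    (split-plot) ANOVA of group by frequency band, Monte Carlo (AlphaSim-style)
    cluster-extent correction, and covariate-adjusted correlation of regional
    amplitudes with clinical scores.  Includes a synthetic resting-state cohort
    generator with planted band-limited effects, motion traces and coupled
    clinical covariates, so the full pipeline is testable end to end without
    patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
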
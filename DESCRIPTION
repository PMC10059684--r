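Package: twaves
Title: Directional Traveling-Wave Analysis of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies forward (occipital-to-frontal) and backward
    (frontal-to-occipital) oscillatory traveling waves in multichannel EEG by
    2D-FFT analysis of electrode space-time maps, referenced to an
    electrode-shuffled surrogate baseline and expressed in decibels. Includes a
    seeded synthetic-EEG generator with known wave content and
    attention-dependent lateralization, a preprocessing chain (resampling,
    zero-phase filtering, average reference, epoching, EOG-based trial
    rejection), Morlet-wavelet time-frequency power, and the statistical layer
    used to analyse covert-attention experiments: repeated-measures ANOVA with
    BIC-approximate Bayes factors, JZS correlation Bayes factors, Fisher
    p-value combination, and trial-by-trial wave-power correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
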
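Package: fracatten
Title: Action-Timing Fractality and Auditory Sensory Attenuation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline linking implicit action-timing control to the
    attenuation of auditory event-related potential (ERP) components in the
    self-stimulation paradigm. Provides detrended fluctuation analysis (DFA)
    of inter-keypress-interval series with the alpha-exponent persistence
    classification, an exact circulant-embedding fractional Gaussian noise
    generator used as its oracle, a shuffle-surrogate repeated-measures ANOVA
    control for sequence-order effects, an ERP processing chain (zero-phase
    band-pass and notch filtering, epoching, baseline correction,
    peak-to-peak artifact rejection, motor correction, collapsed-localizer
    component windows, windowed mean amplitudes), and a statistical layer
    with within-subject ANOVA (Mauchly sphericity test, Greenhouse-Geisser
    correction, partial eta squared), paired contrasts with
    Benjamini-Hochberg adjustment, random-intercept linear mixed models with
    intraclass correlation, and a BIC-based Bayes-factor approximation. A
    synthetic-data generator produces keypress-interval series with known
    fractal structure and multichannel ERP epochs with known component
    effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
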
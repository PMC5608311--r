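Package: dyadvox
Title: Acoustic Analysis of Dyadic Couple-Therapy Interactions and Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting couple-therapy relationship outcomes
    from the speech acoustics of dyadic problem-solving interactions.
    Provides voice activity detection, generalized-likelihood-ratio speaker
    segmentation and two-cluster diarization with pitch-based husband/wife
    role assignment; extraction of 74 frame-level acoustic features
    (MFCC, mel filterbank, line spectral frequencies, pitch, intensity,
    loudness, jitter, shimmer, harmonics-to-noise ratio, and their
    derivatives); static, short-term turn-delta, and long-term pre/post
    session-quarter functionals; behavioral-code feature assembly with
    Krippendorff's alpha agreement; mutual-information and correlation
    based feature selection; couple-grouped cross-validated RBF-SVM
    classification experiments; exact binomial comparisons with
    Clopper-Pearson intervals; and a seeded synthetic dyadic-corpus
    generator (feature level and audio level) for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
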
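Package: cvemp
Title: Cervical Vestibular-Evoked Myogenic Potential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cervical vestibular-evoked myogenic
    potentials (cVEMP) recorded from the sternocleidomastoid under controlled
    muscle tension: artifact rejection and averaging of stimulus-locked EMG
    epochs, normalisation by background EMG tension, a prominence-based
    points system for identifying the p1 peak and n1 trough with anchored
    trough tracking across stimulus levels, response-level (dB RL)
    transformation, linear mixed-effects and Welch group comparisons with
    likelihood-ratio tests, noncentral-t power analysis, and random-effects
    meta-analysis of study-level sex differences with moderator regression.
    Includes a seeded synthetic-data generator emulating the recording
    design so every stage is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    metafor,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
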
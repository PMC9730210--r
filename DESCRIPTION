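Package: esmrecovery
Title: Positive Affective Stress Reactivity and Recovery in Experience
    Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing momentary positive affect around minor
    daily stressors in experience sampling (ESM / ecological momentary
    assessment) diary data. Provides prompt-level data import and
    validation, compliance filtering, scoring of positive-affect and
    stress measures, coding of affect trajectories relative to the first
    daily stressor, three-level linear mixed models (prompts within days
    within persons) with within- and between-group contrasts for stress
    reactivity and affective recovery, step-up multiple-testing
    correction across stress measures, and a synthetic-data generator
    with exported ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
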
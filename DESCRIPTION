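Package: semgprofile
Title: Occupational Surface EMG Activity Profiles and Exposure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying occupational muscle load from surface
    electromyography (sEMG) recordings. Computes moving-window RMS
    envelopes normalized to functional maximum voluntary contractions
    (fMVC), amplitude probability distribution function (APDF)
    percentiles, and percent muscular rest (gap analysis), classifies
    profiles against published static/median/peak load limit values, and
    compares worker groups with a random-block mixed ANOVA including
    Tukey-style adjusted simple main effects of group within muscle. A
    synthetic-data module generates band-limited amplitude-modulated sEMG
    cohorts with analytic ground truth so the whole pipeline is testable
    end to end without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    emmeans,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
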
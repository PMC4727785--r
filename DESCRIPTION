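Package: p50gate
Title: Auditory P50 Sensory Gating: Simulation, ERP Preprocessing, Scoring,
    and Correlation Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying auditory sensory gating with the paired-click
    (conditioning-testing) paradigm. Simulates cohorts of subjects with a
    planted cross-measure correlation structure, raw multichannel EEG with
    stimulus markers, and trial-level behavioural task logs; preprocesses
    continuous recordings (mastoid re-referencing, notch and band-pass
    filtering, regression-based ocular correction, epoching, artifact
    rejection, baseline correction, averaging); scores the P50 component at
    Cz as peak minus preceding N40 trough and derives the S2/S1 gating ratio
    with imputation and truncation rules; computes per-subject inhibition
    indices from task logs; and runs a correlation battery with bivariate and
    partial Pearson correlations, Williams's t tests for dependent
    correlations, paired t tests, and standardized-residual outlier
    screening.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
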
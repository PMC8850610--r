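Package: fcnef
Title: Functional Connectivity Neurofeedback Scoring and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for real-time fMRI functional connectivity neurofeedback
    (FCNef) paradigms that train the anticorrelation between an executive-control
    region (DLPFC) and a default-mode region (precuneus/PCC). Implements per-trial
    connectivity scoring against a SHAM-derived Fisher-z baseline, the 0-100
    feedback score mapping, offline resting-state connectivity with nuisance
    regression, framewise-displacement scrubbing and Butterworth band-pass
    filtering, a block-design GLM localizer with spherical ROI construction, and
    group-level change-score models with likelihood-ratio tests and leave-one-out
    prediction. A synthetic-data module generates BOLD sessions with planted
    connectivity, localizer runs with planted activation, and cohorts with a
    planted connectivity-to-symptom slope, so the full pipeline can be exercised
    end-to-end without access to participant data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    signal,
    yaml,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
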
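Package: anxietyCFE
Title: Convergent Functional Evidence Scoring for Blood Anxiety Biomarkers
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A four-step pipeline for discovering, prioritizing, validating
    and testing blood gene-expression biomarkers of anxiety in
    longitudinally phenotyped psychiatric cohorts. Step 1 scores probesets
    for tracking self-reported anxiety state across diametric within-subject
    visit pairs (differential-expression and detection-call analyses);
    Step 2 adds Convergent Functional Genomics points from curated
    human/animal literature evidence; Step 3 tests candidates for stepwise
    change into a clinically severe anxiety cohort; Step 4 evaluates state
    and trait predictive ability (ROC AUC, Cox proportional hazards) in an
    independent cohort, stratified by gender and diagnosis. Scores compose
    into a Convergent Functional Evidence (CFE) score capped at 36 points.
    Includes biomarker-panel aggregation, a digitized clinician report
    (risk percentiles and pharmacogenomic drug matching), and a synthetic
    longitudinal cohort generator with planted state and trait markers for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
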
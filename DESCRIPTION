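Package: fluencyscreen
Title: Scoring and Validation of Timed Categorical Verbal Fluency Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores timed categorical (semantic) verbal fluency transcripts
    against a subcategory taxonomy, producing the seven standard index
    scores (total, first- and second-half production, perseverations,
    intrusions, mean cluster size, and switching), combines them with
    demographics into a weighted-sum logistic risk score for early
    Alzheimer's disease screening, and provides the psychometric toolkit
    used to validate such instruments: empirical ROC curves with
    Youden-index cutoff selection, paired AUC comparison by the DeLong
    structural-components test, Cronbach's alpha, covariate-adjusted
    (partial) Pearson correlations, ANCOVA group comparisons, and baseline
    tables. A calibrated synthetic-cohort generator emulates the two-group
    case/control structure of a validation study so the whole pipeline can
    be exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
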
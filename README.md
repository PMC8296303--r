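# fluencyscreen

Scoring and psychometric validation of timed categorical (semantic)
verbal fluency screens for early Alzheimer's disease.

Semantic fluency — "name as many animals as you can in 60 seconds" — is
one of the briefest cognitive tests that is sensitive to early AD, and it
can be self-administered by voice on a phone. This package implements the
computational core of such a screening instrument for researchers and
tool builders who need to (a) score transcripts reproducibly, (b) turn
scores into a screening decision, and (c) validate the instrument on a
cohort.

## What it computes

**Index scores.** A timed transcript is labelled against an animal
taxonomy (correct / perseveration / intrusion), segmented into semantic
clusters (maximal runs of correct responses sharing a subcategory;
cluster size = member count − 1), and summarised into seven indices:
total, first-half and second-half correct counts, perseverations,
intrusions, mean cluster size ("clustering"), and cluster switches
("switching").

**Weighted-sum risk score.** The indices combine with demographics into
a fixed logistic logit,

    WS = 1.160 + 0.474·sex + 0.003·age + 0.226·education
         − 0.089·first_half − 0.516·switching − 0.303·clustering
         + 0.534·perseveration

with P(AD-like) = 1 / (1 + e^−WS), screened against a cutoff (default
1.143) and mapped to a traffic-light band. Coefficient sets are data
(two presets plus JSON files; see the methods vignette for why two
presets exist).

**Validation battery.** Empirical ROC curves with midpoint thresholds,
AUC (= Mann–Whitney concordance), Youden-index optimal cutoffs with
sensitivity / specificity / PPV / NPV, paired AUC comparison by the
DeLong structural-components z test, Cronbach's alpha, age/education-
adjusted (partial) Pearson correlations, ANCOVA group comparisons with
adjusted means, baseline t / chi-square tables, and test–retest
reliability.

**Synthetic cohorts.** A calibrated generator (decaying-rate Poisson
production, cluster-and-switch word walk, person-level latent ability,
demographic confounding) emulates the two-group structure of the
instrument's validation cohort, so the whole pipeline is testable
end-to-end without clinical data.

## Worked example

```r
library(fluencyscreen)

tax <- default_taxonomy()
tr <- transcript("p001",
  tokens = c("dog", "cat", "hamster", "lion", "tiger", "table",
             "elephant", "giraffe", "lion", "whale", "dolphin"),
  onsets = c(2.1, 4.0, 7.5, 12.0, 16.4, 21.0, 28.0, 33.5, 39.0, 48.2, 55.0))

compute_index_scores(tr, tax)
#> <index_scores> (window 60 s)
#>         total    first_half   second_half perseveration     intrusion
#>          9.00          6.00          3.00          1.00          1.00
#>    clustering     switching
#>          1.25          3.00

risk_score(list(age = 78, education = 9, sex = 0),
           compute_index_scores(tr, tax))
#> <risk_result> ws = 1.501, P = 0.818, screen positive (cutoff 1.143), band red [preset 'sex_age']
```

Reading the output: nine distinct animals were produced ("table" is an
intrusion, the second "lion" a perseveration), six of them in the first
30 s; the four clusters (pets / big cats / African savanna / sea
mammals) give mean cluster size 1.25 and three switches. For a
78-year-old with 9 years of education those indices put the weighted sum
at 1.50, above the 1.143 screening cutoff — a positive screen with
estimated probability 0.82.

For cohort-level work, `generate_cohort(default_profiles())` simulates a
scored 100 + 100 cohort and `evaluate_cohort()` produces the full
validation report. File-based pipelines can use the `score`, `risk`,
`evaluate` and `simulate` subcommands of `inst/cli/fluencyscreen`.

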
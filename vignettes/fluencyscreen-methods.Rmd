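---
title: "Methods: scoring, risk scoring and validation of timed category fluency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, risk scoring and validation of timed category fluency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluencyscreen)
```

## The task and the seven index scores

In a timed categorical verbal fluency test the participant names as many
members of a semantic category (here: animals) as possible within a fixed
window, 60 s by default. Each transcript is an ordered list of raw tokens
with onset times. Scoring proceeds in three stages.

**Labelling.** Tokens are case-folded, trimmed and matched against a
taxonomy of canonical animal names and their variants. The first
occurrence of an in-lexicon animal is *correct*; the first occurrence of
an out-of-lexicon token is an *intrusion*; any repetition of an earlier
response — correct or incorrect — is a *perseveration*. Repeat detection
uses the canonical token when the response is in-lexicon (so "puppy"
followed by "dog" is a perseveration) and the case-folded raw token
otherwise (so a repeated non-animal also counts).

**Cluster segmentation.** A cluster is a maximal run of successively
produced correct responses sharing an animal subcategory; its size is its
member count minus one, so singletons have size 0. Because entries may
belong to several subcategories (a dog is both a pet and a canine), "the
same subcategory" needs a precise reading. The default is
*running-intersection* semantics: the current cluster is extended while
the intersection of subcategory sets over **all** its members stays
non-empty. This is deterministic, order-respecting, and checkable against
an exhaustive oracle. The alternative reading — each adjacent pair shares
some subcategory, allowing the shared subcategory to drift along the run —
is available as `chain_mode = "pairwise"`.

**Index scores.** From the labels, onsets and clusters:
`total` (correct responses in the window), `first_half` (correct with
onset strictly before `window/2`), `second_half` (the rest), the
`perseveration` and `intrusion` counts, `clustering` (mean cluster size)
and `switching` (number of clusters minus one). Rescoring with
`window = 30` gives the short-form variant of the instrument.

### Conventions for under-specified cases

Published descriptions of this family of scores leave several details
open; the package fixes each one explicitly:

* **Errors inside a cluster.** Perseverations and intrusions are skipped
  and do not interrupt a run, because cluster size is defined over
  *correct* responses. The older tradition in which errors break clusters
  is available via `errors_break_clusters = TRUE`.
* **Half boundary.** An onset exactly at `window/2` belongs to the second
  half (half-open intervals; the assignment at the boundary is arbitrary,
  so it is documented rather than silently chosen).
* **No clusters.** A transcript with no correct responses has clustering
  score 0 and switching 0 rather than `NA`, keeping the downstream risk
  score computable for mute transcripts.
* **Untimed transcripts.** Counts and cluster scores are still computed;
  the half scores are `NA` and the risk score refuses, unless a split by
  response-list midpoint is explicitly requested
  (`untimed_split = "midpoint"`).

## The taxonomy

Clustering is meaningful only relative to a subcategory scheme, and
subcategory granularity materially affects the clustering and switching
scores. The bundled English lexicon (175 canonicals, 29 subcategories,
98 variants) follows the subcategory norms commonly used for animal
fluency (geographic regions, farm animals, pets, felines/canines, birds,
water animals, insects, and so on) with deliberate multi-membership. All
scoring is taxonomy-file-driven: substituting a JSON file substitutes the
language or the norms, and an empty taxonomy is valid for intrusion-only
scoring. Matching is exact after case-folding; there is no fuzzy
matching, because transcripts in the intended workflow are produced by
human transcribers.

## The weighted-sum risk score

The screening score is a fixed logistic-regression logit,

$$\mathrm{WS} = 1.160 + 0.474\,\mathrm{sex} + 0.003\,\mathrm{age}
  + 0.226\,\mathrm{education} - 0.089\,\mathrm{firsthalf}
  - 0.516\,\mathrm{switching} - 0.303\,\mathrm{clustering}
  + 0.534\,\mathrm{perseveration},$$

converted to a probability by the logistic function and classified
against a cutoff (default 1.143, the Youden-optimal cutoff reported for
the instrument's validation cohort; ties classify positive, since a
screen errs toward sensitivity). The total, second-half and intrusion
scores are deliberately excluded from the WS and the implementation never
silently adds them.

The equation as printed in the instrument's documentation contains two
terms that both multiply age (0.474 and 0.003). Taken verbatim, a
75-year-old contributes over 35 logit points, far outside the score
range the same source reports (case mean 2.3, control mean −0.1); the
0.474 term is almost certainly a male-sex indicator. Coefficients are
therefore data, not code: preset `"sex_age"` (default) applies 0.474 to
sex, preset `"as_printed"` reproduces the verbatim equation, a message
always names the active preset, and arbitrary coefficient files can be
loaded. Education is interpreted in years, the unit in which the
validation cohort's education is reported.

## The validation battery

`evaluate_cohort()` reproduces the statistics a validation study of such
an instrument reports. All implementations are deliberately explicit
about their conventions:

* **ROC / AUC.** The empirical curve is built over thresholds at
  midpoints between adjacent distinct observed scores plus infinite
  endpoints — midpoint placement is what makes reported cutoffs such as
  1.143 fall between observed values. Orientation (whether cases score
  high or low) is an explicit per-score attribute, never inferred from
  the data. Trapezoidal area equals the Mann–Whitney concordance
  probability, and the tests assert both routes.
* **Youden cutoff.** The optimum maximises $J = SE + SP - 1$; ties break
  toward higher sensitivity, then the lower cutoff. Published
  diagnostic tables sometimes mark as optimal a row that a strict Youden
  maximisation would not select; the package documents its own
  deterministic rule and does not attempt to reproduce any unstated
  selection rule.
* **Paired AUC comparison.** The "z-test" comparison of correlated AUCs
  is implemented as the DeLong structural-components estimator, the de
  facto standard for ROC curves measured on the same participants. The
  test suite checks it against an independent reference implementation
  and verifies its type-I error by simulation.
* **Cronbach's alpha.** The item set for internal consistency of a
  fluency test is a genuine interpretation choice. When transcripts are
  available, per-10-second-bin correct counts (six bins over 60 s,
  `time_bin_items()`) are the natural items for the production process.
  When only a scored cohort table is available, `evaluate_cohort()` falls
  back to the seven index scores as (standardized) items and records the
  item set in its report.
* **Adjusted analyses.** Test–retest reliability and concurrent validity
  use Pearson correlations of residuals after linear adjustment for age
  and education, with `n - k - 2` degrees of freedom; group comparisons
  of index scores use ANCOVA with the same covariates and report adjusted
  means at covariate means. Baseline tables use pooled-variance t tests
  and *uncorrected* Pearson chi-square tests (the uncorrected statistic
  is what reproduces the reported administration-order p value of 0.04).
  No multiple-testing correction is applied, matching standard practice
  in such validation reports.

## The synthetic cohort generator

No transcript-level data are published for any cohort of this kind, so
the package ships a generative stand-in whose purpose is controllable
ground truth, not linguistic realism.

**Production model.** Onsets follow an inhomogeneous Poisson process
with exponentially decaying rate $r(t) = r_0 e^{-\lambda t}$, sampled
exactly by inversion of the cumulative rate. The decay constant is
chosen per arm so that the expected share of production in the first
30 s matches the reported shares (79.2% cases, 73.7% controls):
$\lambda = -\ln(1/f - 1)/30$ for first-half share $f$. Word identity
follows a cluster-and-switch walk over the taxonomy: repeat an earlier
response with probability `p_perseveration`, otherwise emit a non-animal
filler with probability `p_intrusion`, otherwise draw an unused animal
from the current subcategory with probability `cluster_stay` or switch
to a fresh subcategory (weighted by its remaining members; exhaustion
forces a switch).

**Person structure.** Each participant has a latent ability shared
across administrations and instruments; the log production rate adds
`between_sd` times a mixture of that latent (weight
$\sqrt{\rho}$, $\rho$ = `retest_reliability`) and fresh administration
noise. Age and education shift the log rate in both arms
(−0.01/+0.01 per centred year), so the covariate-adjusted analyses face
real confounding, and MMSE loads on the same latent so the instruments
correlate as they would in a real cohort.

**Calibration.** The default profiles reproduce the validation cohort's
demographics exactly (they are distribution parameters) and were
calibrated once, offline, so that scored synthetic transcripts land near
the reported index-score profile: mean totals near 7.7 / 16.7 and
first-half shares near 79% / 74%, with the recomputed WS discriminating
at an AUC inside a recovery band of [0.75, 0.95]. Two reported targets
cannot be hit jointly: the published clustering, switching and total
means are mutually inconsistent with the stated definitions (the sum of
cluster sizes plus the cluster count must equal the total, but
$(2.9+1)\times(2.0+1) \ne 7.7$). Calibration prioritises totals,
first-half shares and switching — the quantities that enter the WS with
real weight — and lets the clustering mean be emergent (≈1.2, lower than
the reported 2.0/1.7). First-half shares are measured as ratios of group
means, the same construction by which the reported percentages derive
from the reported index means; per-participant mean ratios are biased by
near-mute transcripts.

**What passing does and does not show.** The generator emulates
summary-level structure: group separations, production-rate decay,
retest correlation, demographic confounding. It does not model
transcription errors, semantic association structure within
subcategories, Korean morphology, or the covariance of index scores
(reported SDs are targeted only loosely; induced correlations are
emergent). Recovery-band tests therefore validate the *pipeline* —
scoring, risk scoring and the statistics — under a plausible data model,
not the clinical accuracy of the instrument.

## Problem sizes and numerical choices

The test suite exercises exhaustive oracles where exhaustion is feasible
and fixed-seed simulation elsewhere: all 1,956 injective token sequences
of a three-subcategory toy lexicon for cluster segmentation (every
transcript that lexicon can produce), 200 random instances each for the
AUC-concordance and Youden-exhaustive-search equivalences, 2,000
replicates at 100+100 for the type-I calibration of the DeLong and
ANCOVA tests, and one 200-per-arm cohort for parameter recovery. p
values are reported to machine precision. Degenerate inputs are defined,
not errored, wherever the downstream pipeline needs them (empty
transcripts, empty taxonomies, zero-denominator predictive values return
`NA`); genuinely uninterpretable inputs (single-class ROC, collinear
covariates, zero total variance in alpha) fail loudly.

## Known limitations

* Coefficients and the default cutoff are frozen from the instrument's
  published equation; refitting on new cohorts is out of scope.
* The Youden tie rule and the half-boundary assignment are this
  package's documented choices; other implementations may differ on
  exactly tied data.
* The generator's clustering mean is below the published value for the
  reason given above; analyses that hinge on the clustering index's
  absolute level should not rely on the simulator.
* Cronbach's alpha from index-score items is an interpretation, flagged
  in the evaluation report; time-bin items require transcripts.
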
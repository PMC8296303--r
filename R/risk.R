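#' Coefficient presets for the weighted-sum risk score
#'
#' The weighted sum (WS) is a fixed logistic-regression logit combining
#' demographics with four fluency indices:
#'
#' \deqn{WS = b_0 + b_{sex} sex + b_{age} age + b_{edu} education
#'   + b_{fh} first\_half + b_{sw} switching + b_{cl} clustering
#'   + b_{pe} perseveration}
#'
#' Two presets ship with the package. The instrument's published equation
#' prints two terms that both multiply age (0.474 and 0.003); taken
#' verbatim this drives the score far outside the range the same source
#' reports for it, and the 0.474 term is almost certainly a male-sex
#' indicator in the original model. `"sex_age"` (the default) applies
#' 0.474 to the sex indicator and 0.003 to age; `"as_printed"` applies
#' both to age, exactly as printed. Coefficients are data, not code: any
#' set can be loaded from JSON with [load_coefficients()].
#'
#' @param preset `"sex_age"` (default) or `"as_printed"`.
#' @param quiet suppress the message naming the active preset.
#' @return A `coefficient_set`: list with `intercept`, `coefficients`
#'   (named numeric over the seven predictors) and `preset`.
#' @export
coefficient_preset <- function(preset = c("sex_age", "as_printed"),
                               quiet = FALSE) {
  preset <- match.arg(preset)
  base <- c(sex = 0, age = 0.003, education = 0.226,
            first_half = -0.089, switching = -0.516,
            clustering = -0.303, perseveration = 0.534)
  co <- switch(preset,
    sex_age    = replace(base, "sex", 0.474),
    as_printed = replace(base, "age", base[["age"]] + 0.474))
  if (!quiet)
    message("weighted-sum coefficient preset in use: '", preset, "'")
  .coefficient_set(1.160, co, preset)
}

.ws_predictors <- c("sex", "age", "education", "first_half", "switching",
                    "clustering", "perseveration")

.coefficient_set <- function(intercept, coefficients, preset) {
  miss <- setdiff(.ws_predictors, names(coefficients))
  if (length(miss))
    stop("coefficient set is missing predictor(s): ",
         paste(miss, collapse = ", "))
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients[.ws_predictors],
                 preset = preset),
            class = "coefficient_set")
}

#' Load a coefficient set from JSON
#'
#' Schema: `{"preset": str, "intercept": num, "coefficients": {name: num}}`
#' with all seven predictor names present (`sex`, `age`, `education`,
#' `first_half`, `switching`, `clustering`, `perseveration`; zeros
#' allowed).
#'
#' @param path JSON path.
#' @return A `coefficient_set`.
#' @export
load_coefficients <- function(path) {
  o <- jsonlite::fromJSON(path)
  .coefficient_set(o$intercept, unlist(o$coefficients),
                   if (is.null(o$preset)) basename(path) else o$preset)
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set> preset '", x$preset, "', intercept ",
      x$intercept, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Weighted-sum risk logit
#'
#' Pure dot product of the coefficient set with the participant's
#' predictors. Higher values are more case-like (the fluency coefficients
#' are negative for indices on which cases do worse).
#'
#' @param demo list or one-row data.frame with `age` (years), `education`
#'   (years) and `sex` (0 = female, 1 = male).
#' @param scores an `index_scores` object, or any list with `first_half`,
#'   `switching`, `clustering`, `perseveration`.
#' @param coeffs a `coefficient_set` (default: the `"sex_age"` preset).
#' @return the WS logit (numeric scalar).
#' @export
weighted_sum <- function(demo, scores,
                         coeffs = coefficient_preset(quiet = TRUE)) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  p <- c(sex = as.numeric(demo$sex), age = as.numeric(demo$age),
         education = as.numeric(demo$education),
         first_half = as.numeric(scores$first_half),
         switching = as.numeric(scores$switching),
         clustering = as.numeric(scores$clustering),
         perseveration = as.numeric(scores$perseveration))
  if (anyNA(p)) {
    bad <- names(p)[is.na(p)]
    stop("cannot compute weighted sum: missing predictor(s): ",
         paste(bad, collapse = ", "),
         if ("first_half" %in% bad)
           " (untimed transcript? see compute_index_scores(untimed_split=))")
  }
  coeffs$intercept + sum(coeffs$coefficients[names(p)] * p)
}

#' Convert a WS logit to a probability
#'
#' @param ws finite WS logit(s).
#' @return `1 / (1 + exp(-ws))`.
#' @export
ws_probability <- function(ws) stats::plogis(ws)

#' Classify a WS logit against a cutoff
#'
#' Ties at the cutoff classify positive: a screening instrument errs
#' toward sensitivity.
#'
#' @param ws WS logit(s).
#' @param cutoff decision cutoff (default 1.143, the instrument's
#'   published optimal cutoff from its validation cohort).
#' @return character vector, `"positive"` or `"negative"`.
#' @export
classify_ws <- function(ws, cutoff = 1.143) {
  stopifnot(is.finite(cutoff))
  ifelse(ws >= cutoff, "positive", "negative")
}

#' Traffic-light band for a risk probability
#'
#' @param probability probabilities in `[0, 1]`.
#' @param low,high band thresholds, `0 <= low < high <= 1` (defaults 0.33
#'   and 0.66).
#' @return character vector: `"green"` (p < low), `"yellow"`
#'   (low <= p < high) or `"red"` (p >= high).
#' @export
traffic_band <- function(probability, low = 0.33, high = 0.66) {
  if (!(low >= 0 && low < high && high <= 1))
    stop("band thresholds must satisfy 0 <= low < high <= 1")
  ifelse(probability >= high, "red",
         ifelse(probability >= low, "yellow", "green"))
}

#' Full risk result for one participant
#'
#' @inheritParams weighted_sum
#' @inheritParams classify_ws
#' @inheritParams traffic_band
#' @return A `risk_result`: list with `ws`, `probability`, `cutoff`,
#'   `screen`, `band` and `preset`.
#' @export
risk_score <- function(demo, scores,
                       coeffs = coefficient_preset(quiet = TRUE),
                       cutoff = 1.143, low = 0.33, high = 0.66) {
  ws <- weighted_sum(demo, scores, coeffs)
  p <- ws_probability(ws)
  structure(list(ws = ws, probability = p, cutoff = cutoff,
                 screen = classify_ws(ws, cutoff),
                 band = traffic_band(p, low, high),
                 preset = coeffs$preset),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat("<risk_result> ws = ", format(x$ws, digits = 4),
      ", P = ", format(x$probability, digits = 3),
      ", screen ", x$screen, " (cutoff ", x$cutoff, "), band ", x$band,
      " [preset '", x$preset, "']\n", sep = "")
  invisible(x)
}
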
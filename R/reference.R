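#' Published validation-cohort summary values
#'
#' Summary statistics reported for the instrument's original validation
#' cohort (100 early-AD cases vs 100 cognitively normal controls). They
#' are inputs, not results: the diagnostic-table rows carry the reported
#' cutoff / sensitivity / specificity from which predictive values can be
#' recomputed, and the index-score profile supplies the calibration
#' targets of [default_profiles()] and the group-mean inputs of worked
#' examples.
#'
#' @return `reference_cutoff_rows()`: data.frame with columns
#'   `instrument` (`tcvft_ws`, `ccvft_ws`, `mmse`), `cutoff`,
#'   `sensitivity`, `specificity` and `optimal` (the Youden-selected row),
#'   plus `n_cases`/`n_controls` of the design.
#' @export
reference_cutoff_rows <- function() {
  df <- data.frame(
    instrument = rep(c("tcvft_ws", "ccvft_ws", "mmse"), each = 5),
    cutoff = c(1.101, 1.115, 1.143, 1.241, 1.325,
               2.095, 2.111, 2.116, 2.121, 2.132,
               23.5, 24.5, 25.5, 26.5, 27.5),
    sensitivity = c(0.780, 0.780, 0.780, 0.780, 0.770,
                    0.660, 0.660, 0.660, 0.660, 0.660,
                    0.950, 0.910, 0.870, 0.780, 0.600),
    specificity = c(0.750, 0.760, 0.770, 0.780, 0.780,
                    0.620, 0.630, 0.640, 0.650, 0.660,
                    0.770, 0.810, 0.880, 0.920, 0.960),
    optimal = rep(c(FALSE, FALSE, TRUE, FALSE, FALSE), 3))
  df$n_cases <- 100L
  df$n_controls <- 100L
  df
}

#' @rdname reference_cutoff_rows
#' @return `reference_index_profiles()`: data.frame with columns `score`,
#'   `case_mean`, `case_sd`, `control_mean`, `control_sd` for the weighted
#'   sum and the seven index scores.
#' @export
reference_index_profiles <- function() {
  data.frame(
    score = c("ws", "total", "first_half", "second_half", "clustering",
              "switching", "perseveration", "intrusion"),
    case_mean = c(2.3, 7.7, 6.1, 1.8, 2.0, 2.9, 1.2, 0.3),
    case_sd = c(1.4, 3.6, 2.5, 1.9, 1.7, 1.9, 1.4, 0.5),
    control_mean = c(-0.1, 16.7, 12.3, 4.3, 1.7, 7.7, 1.0, 1.0),
    control_sd = c(1.7, 4.6, 3.1, 2.5, 1.3, 3.6, 1.2, 1.3))
}
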
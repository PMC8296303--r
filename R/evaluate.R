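#' Full psychometric evaluation of a scored cohort
#'
#' Runs the validation battery a screening-instrument study reports on a
#' two-group scored cohort: per-score ROC analysis with a Youden-optimal
#' cutoff table (the optimal threshold and its nearest neighbours, with
#' sensitivity / specificity / PPV / NPV), pairwise paired AUC
#' comparisons (DeLong), covariate-adjusted ANCOVA group comparisons of
#' the index scores, covariate-adjusted correlations among the headline
#' scores, internal consistency (standardized Cronbach's alpha over the
#' index-score item set), test-retest reliability for every score with
#' two administrations, and a baseline characteristics table.
#'
#' @param cohort cohort data.frame (see [read_cohort_csv()] for the
#'   layout).
#' @param scores character vector of score columns for ROC analysis;
#'   default: every `*_ws_1` / `*_total_1` column plus `mmse` when
#'   present.
#' @param covariates covariate columns for adjusted analyses.
#' @param alpha_items columns used as Cronbach's-alpha items; default the
#'   seven `tcvft_*_1` index scores. Time-bin items (see
#'   [time_bin_items()]) can be supplied as a matrix instead.
#' @param n_cutoff_rows rows of the cutoff table around the optimum.
#' @return nested list (serializable to JSON) with elements `n`,
#'   `baseline`, `roc`, `auc_comparisons`, `group_comparisons`,
#'   `correlations` and `reliability`.
#' @export
evaluate_cohort <- function(cohort,
                            scores = NULL,
                            covariates = c("age", "education_years"),
                            alpha_items = NULL,
                            n_cutoff_rows = 5L) {
  g <- cohort$group
  if (length(unique(g)) != 2)
    stop("evaluation needs both a case and a control group")
  if (is.null(scores)) {
    scores <- grep("_(ws|total)_1$", names(cohort), value = TRUE)
    if ("mmse" %in% names(cohort)) scores <- c(scores, "mmse")
  }
  covariates <- intersect(covariates, names(cohort))
  zc <- if (length(covariates)) cohort[covariates] else NULL

  roc_block <- list()
  for (sc in scores) {
    orient <- default_orientation(sc)
    curve <- roc_curve(cohort[[sc]], g, orientation = orient)
    a <- auc(curve)
    se <- sqrt(auc_variance_delong(cohort[[sc]], g, orientation = orient))
    opt <- youden_optimal_cutoff(curve)
    j <- curve$sensitivity + curve$specificity - 1
    i_opt <- order(-j, -curve$sensitivity, curve$threshold)[1]
    half <- (n_cutoff_rows - 1L) %/% 2L
    idx <- seq(max(1L, i_opt - half),
               min(nrow(curve), i_opt + half))
    tab <- lapply(idx, function(i) {
      m <- cutoff_metrics(curve$sensitivity[i], curve$specificity[i],
                          attr(curve, "n_cases"), attr(curve, "n_controls"),
                          cutoff = curve$threshold[i])
      list(cutoff = m$cutoff, sensitivity = m$sensitivity,
           specificity = m$specificity, ppv = m$ppv, npv = m$npv,
           youden = m$youden, optimal = (i == i_opt))
    })
    roc_block[[sc]] <- list(
      orientation = orient, auc = a,
      auc_ci95 = c(max(0, a - 1.96 * se), min(1, a + 1.96 * se)),
      optimal_cutoff = opt$cutoff, cutoff_table = tab)
  }

  cmp_block <- list()
  if (length(scores) >= 2) {
    prs <- utils::combn(scores, 2, simplify = FALSE)
    for (pr in prs) {
      cmp <- delong_compare(cohort[[pr[1]]], cohort[[pr[2]]], g,
                            orientation_a = default_orientation(pr[1]),
                            orientation_b = default_orientation(pr[2]))
      cmp_block[[paste(pr, collapse = "_vs_")]] <-
        list(score_a = pr[1], score_b = pr[2], auc_a = cmp$auc_a,
             auc_b = cmp$auc_b, z = cmp$z, p = cmp$p)
    }
  }

  idx_cols <- grep("^tcvft_.*_1$", names(cohort), value = TRUE)
  grp_block <- lapply(stats::setNames(nm = idx_cols), function(col) {
    a <- ancova_compare(cohort[[col]], g, zc)
    list(F = a$F, p = a$p, adjusted_means = as.list(a$adjusted_means))
  })

  cor_block <- list()
  if (length(scores) >= 2) {
    prs <- utils::combn(scores, 2, simplify = FALSE)
    for (pr in prs) {
      pc <- partial_pearson(cohort[[pr[1]]], cohort[[pr[2]]], zc)
      cor_block[[paste(pr, collapse = "_vs_")]] <-
        list(r = pc$r, p = pc$p, df = pc$df)
    }
  }

  if (is.null(alpha_items)) {
    items <- cohort[grep(
      "^tcvft_(total|first_half|second_half|perseveration|intrusion|clustering|switching)_1$",
      names(cohort))]
    alpha_items <- as.matrix(items)
  }
  alpha <- tryCatch(cronbach_alpha(alpha_items, standardize = TRUE),
                    error = function(e) NA_real_)

  stems <- sub("_1$", "", grep("_1$", names(cohort), value = TRUE))
  stems <- stems[paste0(stems, "_2") %in% names(cohort)]
  retest_block <- lapply(stats::setNames(nm = stems), function(st) {
    r <- test_retest(cohort, st, covariates)
    list(r = r$r, p = r$p, n_used = r$n_used, n_excluded = r$n_excluded)
  })

  list(n = as.list(table(g)),
       baseline = baseline_compare(cohort),
       roc = roc_block,
       auc_comparisons = cmp_block,
       group_comparisons = grp_block,
       correlations = cor_block,
       reliability = list(cronbach_alpha = alpha,
                          alpha_items = if (is.matrix(alpha_items))
                            colnames(alpha_items) else names(alpha_items),
                          test_retest = retest_block))
}
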
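#' Empirical ROC curve
#'
#' Builds the empirical ROC over all distinct score values, with
#' thresholds placed at midpoints between adjacent distinct observed
#' scores plus infinite endpoints (midpoint thresholds are how reported
#' diagnostic cutoffs typically fall between observed values).
#' Orientation is explicit and never inferred: with
#' `orientation = "higher"` larger scores are treated as case-like and a
#' score is test-positive when `score >= threshold`; with `"lower"` the
#' predicate is `score <= threshold`.
#'
#' @param scores numeric vector, no missing values.
#' @param labels vector of `"case"` / `"control"` labels, same length.
#' @param orientation `"higher"` (cases score high) or `"lower"`.
#' @return A `roc_curve`: data.frame with columns `threshold`,
#'   `sensitivity`, `specificity`, and attributes `orientation`,
#'   `n_cases`, `n_controls`, `scores`, `labels`.
#' @export
roc_curve <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad))
    stop("labels must be 'case'/'control'; found: ",
         paste(bad, collapse = ", "))
  is_case <- labels == "case"
  if (!any(is_case) || all(is_case))
    stop("ROC analysis needs at least one case and one control")
  s <- if (orientation == "higher") scores else -scores
  u <- sort(unique(s))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(s[is_case] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!is_case] < t), numeric(1))
  out <- data.frame(
    threshold = if (orientation == "higher") thr else rev(-thr),
    sensitivity = if (orientation == "higher") sens else rev(sens),
    specificity = if (orientation == "higher") spec else rev(spec))
  structure(out, class = c("roc_curve", "data.frame"),
            orientation = orientation,
            n_cases = sum(is_case), n_controls = sum(!is_case),
            scores = scores, labels = labels)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical curve; with midpoint thresholds
#' this equals the Mann-Whitney concordance probability (ties counted
#' one-half).
#'
#' @param x a `roc_curve`, or a numeric score vector (then `labels` and
#'   `orientation` are required as in [roc_curve()]).
#' @param labels,orientation used when `x` is a score vector.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(x, labels = NULL, orientation = c("higher", "lower")) {
  if (!inherits(x, "roc_curve"))
    x <- roc_curve(x, labels, orientation)
  fpr <- 1 - x$specificity
  tpr <- x$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Diagnostic accuracy metrics at a cutoff
#'
#' From sensitivity, specificity and the class sizes, reconstructs the
#' confusion counts (`TP = se * n_cases`, `FP = (1 - sp) * n_controls`,
#' ...) and derives the predictive values and the Youden index
#' `J = se + sp - 1`. Zero denominators yield `NA` predictive values
#' (flagged, not thrown).
#'
#' @param sensitivity,specificity values in `[0, 1]`.
#' @param n_cases,n_controls class sizes (>= 1).
#' @param cutoff the threshold these metrics describe (carried through,
#'   `NA` if not applicable).
#' @return A `cutoff_metrics`: list with `cutoff`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `youden` and the four confusion counts.
#' @export
cutoff_metrics <- function(sensitivity, specificity, n_cases, n_controls,
                           cutoff = NA_real_) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            n_cases >= 1, n_controls >= 1)
  tp <- sensitivity * n_cases
  fn <- n_cases - tp
  tn <- specificity * n_controls
  fp <- n_controls - tn
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  structure(list(cutoff = cutoff, sensitivity = sensitivity,
                 specificity = specificity, ppv = ppv, npv = npv,
                 youden = sensitivity + specificity - 1,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "cutoff_metrics")
}

#' @export
print.cutoff_metrics <- function(x, ...) {
  cat("<cutoff_metrics> cutoff ", format(x$cutoff, digits = 4),
      ": SE ", format(x$sensitivity, digits = 3),
      ", SP ", format(x$specificity, digits = 3),
      ", PPV ", format(x$ppv, digits = 3),
      ", NPV ", format(x$npv, digits = 3),
      ", J ", format(x$youden, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Optimal cutoff by the Youden index maximum
#'
#' Scans every threshold of the empirical curve and returns the metrics at
#' the threshold maximizing `J = sensitivity + specificity - 1`. Ties are
#' broken toward higher sensitivity, then toward the lower cutoff (both
#' deterministic; a screening instrument prefers sensitivity).
#'
#' @param curve a `roc_curve`.
#' @return A `cutoff_metrics` at the optimal threshold.
#' @export
youden_optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  o <- order(-j, -curve$sensitivity, curve$threshold)
  i <- o[1]
  cutoff_metrics(curve$sensitivity[i], curve$specificity[i],
                 attr(curve, "n_cases"), attr(curve, "n_controls"),
                 cutoff = curve$threshold[i])
}

# DeLong structural components via midranks: V10[i] = placement of case i
# among controls, V01[j] = placement of control j among cases.
.delong_components <- function(scores, is_case) {
  x <- scores[is_case]; y <- scores[!is_case]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of a single empirical AUC
#'
#' @param scores numeric scores.
#' @param labels `"case"`/`"control"` labels.
#' @param orientation as in [roc_curve()].
#' @return estimated variance of the empirical AUC.
#' @export
auc_variance_delong <- function(scores, labels,
                                orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  s <- if (orientation == "higher") scores else -scores
  is_case <- as.character(labels) == "case"
  cmp <- .delong_components(s, is_case)
  stats::var(cmp$v10) / length(cmp$v10) +
    stats::var(cmp$v01) / length(cmp$v01)
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Compares the AUCs of two scores measured on the same participants using
#' the structural-components (DeLong) covariance estimate for correlated
#' empirical ROC curves; the two-sided p value comes from the standard
#' normal reference.
#'
#' @param scores_a,scores_b paired numeric scores (same participants, same
#'   order).
#' @param labels `"case"`/`"control"` labels.
#' @param orientation_a,orientation_b per-score orientation as in
#'   [roc_curve()].
#' @return An `auc_comparison`: list with `auc_a`, `auc_b`, `z`, `p` and
#'   `var_diff`.
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           orientation_a = c("higher", "lower"),
                           orientation_b = c("higher", "lower")) {
  orientation_a <- match.arg(orientation_a)
  orientation_b <- match.arg(orientation_b)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must be paired (equal lengths)")
  is_case <- as.character(labels) == "case"
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    stop("DeLong comparison needs at least 2 cases and 2 controls")
  sa <- if (orientation_a == "higher") scores_a else -scores_a
  sb <- if (orientation_b == "higher") scores_b else -scores_b
  ca <- .delong_components(sa, is_case)
  cb <- .delong_components(sb, is_case)
  m <- sum(is_case); n <- sum(!is_case)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  z <- if (var_diff > 0) d / sqrt(var_diff) else if (d == 0) 0
       else sign(d) * Inf
  structure(list(auc_a = ca$auc, auc_b = cb$auc, z = z,
                 p = 2 * stats::pnorm(-abs(z)), var_diff = var_diff),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat("<auc_comparison> AUC ", format(x$auc_a, digits = 4), " vs ",
      format(x$auc_b, digits = 4), ": z = ", format(x$z, digits = 4),
      ", p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`.
#'
#' @param items numeric matrix, participants x items; at least 2 items, 3
#'   participants, no missing values.
#' @param standardize scale each item to unit variance first
#'   (standardized alpha).
#' @return alpha, or `NA` (with a warning) when the total variance is
#'   zero.
#' @export
cronbach_alpha <- function(items, standardize = FALSE) {
  items <- as.matrix(items)
  if (ncol(items) < 2) stop("Cronbach's alpha needs at least 2 items")
  if (nrow(items) < 3) stop("Cronbach's alpha needs at least 3 participants")
  if (anyNA(items)) stop("items must not contain missing values")
  if (standardize) {
    sds <- apply(items, 2, stats::sd)
    if (any(sds == 0)) stop("cannot standardize a constant item")
    items <- sweep(items, 2, sds, "/")
  }
  vt <- stats::var(rowSums(items))
  if (vt == 0) {
    warning("zero total-score variance; alpha undefined")
    return(NA_real_)
  }
  k <- ncol(items)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / vt)
}

#' Partial (covariate-adjusted) Pearson correlation
#'
#' Correlates the residuals of `x` and `y` after linear adjustment on the
#' covariates plus an intercept; the p value uses the t reference with
#' `n - k - 2` degrees of freedom (`k` covariates). With no covariates
#' this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix / data.frame of covariates, or `NULL`.
#' @return list with `r`, `p`, `df` and `n`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    k <- 0L
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    z <- as.matrix(covariates)
    stopifnot(nrow(z) == n)
    k <- ncol(z)
    zz <- cbind(1, z)
    if (qr(zz)$rank < ncol(zz))
      stop("covariates are collinear (rank-deficient design)")
    rx <- stats::lm.fit(zz, x)$residuals
    ry <- stats::lm.fit(zz, y)$residuals
  }
  df <- n - k - 2L
  if (df < 1) stop("not enough observations for the covariate set")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df, n = n)
}

#' ANCOVA group comparison
#'
#' F test of a two-level group term in a linear model with covariates,
#' with adjusted group means evaluated at the covariate means. With no
#' covariates the F statistic equals the square of the pooled two-sample
#' t statistic.
#'
#' @param values numeric response.
#' @param group two-level factor / character vector.
#' @param covariates numeric matrix / data.frame, or `NULL`.
#' @return list with `F`, `p`, `df` (numerator, denominator) and
#'   `adjusted_means` (named by group level).
#' @export
ancova_compare <- function(values, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  df <- data.frame(.y = values, .g = group)
  if (!is.null(covariates)) {
    z <- as.data.frame(covariates)
    names(z) <- paste0(".z", seq_along(z))
    if (qr(cbind(1, as.matrix(z)))$rank < ncol(z) + 1)
      stop("covariates are collinear (rank-deficient design)")
    df <- cbind(df, z)
  }
  full <- stats::lm(.y ~ ., data = df)
  reduced <- stats::lm(.y ~ . - .g, data = df)
  a <- stats::anova(reduced, full)
  newdata <- df[c(1, 1), -1, drop = FALSE]
  newdata$.g <- factor(levels(group), levels = levels(group))
  if (ncol(newdata) > 1)
    for (j in names(newdata)[-1]) newdata[[j]] <- mean(df[[j]])
  adj <- stats::predict(full, newdata = newdata)
  names(adj) <- levels(group)
  list(F = a$F[2], p = a$`Pr(>F)`[2],
       df = c(a$Df[2], a$Res.Df[2]), adjusted_means = adj)
}

#' Baseline characteristics comparison between groups
#'
#' Two-sample Student's t tests (pooled variance) for continuous
#' variables and Pearson chi-square tests (uncorrected) for categorical
#' variables, case vs control.
#'
#' @param cohort cohort data.frame with a `group` column
#'   (`"case"`/`"control"`).
#' @param continuous,categorical character vectors of column names; by
#'   default the standard demographic columns present in the cohort.
#' @return data.frame with one row per variable: `variable`, `type`,
#'   group summaries (`mean ± SD` or `%`), `statistic`, `p` and
#'   `low_expected` flag for sparse chi-square cells.
#' @export
baseline_compare <- function(cohort,
                             continuous = intersect(
                               c("age", "education_years", "mmse"),
                               names(cohort)),
                             categorical = intersect("sex", names(cohort))) {
  g <- factor(cohort$group, levels = c("control", "case"))
  if (nlevels(droplevels(g)) != 2) stop("both groups must be present")
  fmt <- function(v) sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
  rows <- list()
  for (v in continuous) {
    tt <- stats::t.test(cohort[[v]] ~ g, var.equal = TRUE)
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      control = fmt(cohort[[v]][g == "control"]),
      case = fmt(cohort[[v]][g == "case"]),
      statistic = unname(tt$statistic), p = tt$p.value,
      low_expected = FALSE, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    tab <- table(g, cohort[[v]])
    suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
    pct <- function(lev) {
      x <- cohort[[v]][g == lev]
      sprintf("%.0f%%", 100 * mean(x == max(x)))
    }
    rows[[v]] <- data.frame(
      variable = v, type = "categorical",
      control = pct("control"), case = pct("case"),
      statistic = unname(ct$statistic), p = ct$p.value,
      low_expected = any(ct$expected < 1), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Test-retest reliability of a score
#'
#' Covariate-adjusted Pearson correlation between the first and second
#' administrations of a score; participants missing either administration
#' are excluded listwise and counted.
#'
#' @param cohort cohort data.frame with columns `<score>_1` and
#'   `<score>_2`.
#' @param score score column stem, e.g. `"tcvft_total"`.
#' @param covariates character vector of covariate column names (default
#'   age and education).
#' @return list with `r`, `p`, `df`, `n_used` and `n_excluded`.
#' @export
test_retest <- function(cohort, score,
                        covariates = c("age", "education_years")) {
  c1 <- paste0(score, "_1"); c2 <- paste0(score, "_2")
  miss <- setdiff(c(c1, c2), names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(cohort[c(c1, c2, covariates)])
  d <- cohort[ok, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 participants with both administrations")
  z <- if (length(covariates)) d[covariates] else NULL
  res <- partial_pearson(d[[c1]], d[[c2]], z)
  c(res, list(n_used = nrow(d), n_excluded = sum(!ok)))
}

#' Default case/control orientation of a score
#'
#' Cases (early AD) are expected to score *higher* on the weighted sum,
#' age and mean cluster size, and *lower* on MMSE, total, half, switching
#' and intrusion scores. Orientation is an explicit attribute of every
#' analysis; this helper only supplies the conventional default.
#'
#' @param score score name (suffix after the instrument prefix, e.g.
#'   `"ws"`, `"total"`, `"mmse"`).
#' @return `"higher"` or `"lower"`.
#' @export
default_orientation <- function(score) {
  stem <- sub("^(tcvft|ccvft)_", "", score)
  stem <- sub("_[0-9]+$", "", stem)
  if (stem %in% c("ws", "age", "clustering", "perseveration")) "higher"
  else "lower"
}
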
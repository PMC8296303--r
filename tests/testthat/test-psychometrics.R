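test_that("ROC curves and AUC match direct construction on small cases", {
  # complete separation
  cv <- roc_curve(c(2, 3, 0, 1), c("case", "case", "control", "control"))
  expect_equal(auc(cv), 1)
  expect_equal(youden_optimal_cutoff(cv)$youden, 1)
  # no discrimination
  cv0 <- roc_curve(rep(1, 10), rep(c("case", "control"), 5))
  expect_equal(auc(cv0), 0.5)
  expect_equal(youden_optimal_cutoff(cv0)$youden, 0)
  # tie across groups: all-pairs concordance gives 0.75
  expect_equal(auc(c(2, 3, 1, 2.5), c("case", "case", "control", "control")),
               0.75)
  # single-class input is degenerate
  expect_error(roc_curve(1:3, rep("case", 3)), "at least one")
})

test_that("AUC equals the all-pairs concordance probability on random data", {
  set.seed(11)
  for (i in 1:50) {
    m <- sample(3:30, 1); n <- sample(3:30, 1)
    sc <- c(rnorm(m, 0.5), rnorm(n))
    if (i %% 3 == 0) sc <- round(sc)  # force ties
    lb <- rep(c("case", "control"), c(m, n))
    expect_equal(auc(sc, lb), oracle_auc(sc, lb))
  }
})

test_that("orientation reversal maps AUC to its complement (tie-free)", {
  set.seed(12)
  sc <- rnorm(40)
  lb <- rep(c("case", "control"), 20)
  expect_equal(auc(sc, lb, "higher") + auc(sc, lb, "lower"), 1)
  expect_equal(auc(sc, lb, "lower"), auc(-sc, lb, "higher"))
})

test_that("Youden-optimal cutoff equals exhaustive search with documented ties", {
  set.seed(13)
  for (i in 1:50) {
    sc <- round(c(rnorm(12, 0.8), rnorm(8)), 1)
    lb <- rep(c("case", "control"), c(12, 8))
    got <- youden_optimal_cutoff(roc_curve(sc, lb))
    want <- oracle_youden(sc, lb)
    expect_equal(got$youden, want$j)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$sensitivity, want$sensitivity)
  }
})

test_that("cutoff metrics satisfy the confusion identities", {
  m <- cutoff_metrics(1, 1, 50, 70)
  expect_equal(m$ppv, 1); expect_equal(m$npv, 1)
  set.seed(14)
  for (i in 1:20) {
    se <- runif(1); sp <- runif(1)
    nc <- sample(5:200, 1); nn <- sample(5:200, 1)
    m <- cutoff_metrics(se, sp, nc, nn)
    expect_equal(m$ppv * (m$tp + m$fp), m$tp)
    # prevalence identity: PPV from Bayes with prevalence nc/(nc+nn)
    prev <- nc / (nc + nn)
    expect_equal(m$ppv,
                 se * prev / (se * prev + (1 - sp) * (1 - prev)))
  }
  # zero denominator flags, not throws
  expect_true(is.na(cutoff_metrics(0, 1, 10, 10)$ppv))
})

test_that("DeLong comparison is exact for self-comparison and antisymmetric", {
  set.seed(15)
  sc <- rnorm(60); lb <- rep(c("case", "control"), 30)
  self <- delong_compare(sc, sc, lb)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  sc2 <- sc + rnorm(60, 0, 0.5)
  ab <- delong_compare(sc, sc2, lb)
  ba <- delong_compare(sc2, sc, lb)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_error(delong_compare(sc, sc2[-1], lb), "paired")
})

test_that("DeLong AUCs, variance and p agree with the reference implementation", {
  set.seed(16)
  lb <- rep(c("case", "control"), c(40, 50))
  sa <- c(rnorm(40, 1), rnorm(50))
  sb <- 0.6 * sa + rnorm(90, 0, 0.8)
  got <- delong_compare(sa, sb, lb)
  ref <- pROC::roc.test(
    pROC::roc(lb, sa, levels = c("control", "case"), direction = "<",
              quiet = TRUE),
    pROC::roc(lb, sb, levels = c("control", "case"), direction = "<",
              quiet = TRUE),
    method = "delong")
  expect_equal(got$auc_a, as.numeric(ref$estimate[1]))
  expect_equal(got$auc_b, as.numeric(ref$estimate[2]))
  expect_equal(got$z, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # single-curve variance against the reference variance
  expect_equal(auc_variance_delong(sa, lb),
               as.numeric(pROC::var(pROC::roc(lb, sa,
                 levels = c("control", "case"), direction = "<",
                 quiet = TRUE), method = "delong")),
               tolerance = 1e-10)
})

test_that("DeLong variance tracks the sampling variance of the AUC", {
  set.seed(17)
  reps <- 800
  aucs <- numeric(reps); vars <- numeric(reps)
  lb <- rep(c("case", "control"), c(50, 50))
  for (r in seq_len(reps)) {
    sc <- c(rnorm(50, 0.8), rnorm(50))
    aucs[r] <- auc(sc, lb)
    vars[r] <- auc_variance_delong(sc, lb)
  }
  expect_lt(abs(mean(vars) / var(aucs) - 1), 0.15)
})

test_that("Cronbach's alpha matches its closed forms", {
  set.seed(18)
  # two standardized items with correlation r -> alpha = 2r/(1+r)
  x <- rnorm(200); y <- 0.7 * x + rnorm(200, 0, sqrt(1 - 0.49))
  m <- cbind(scale(x)[, 1], scale(y)[, 1])
  r <- cor(m[, 1], m[, 2])
  expect_equal(cronbach_alpha(m), 2 * r / (1 + r), tolerance = 1e-12)
  # k identical items -> alpha = 1
  z <- rnorm(30)
  expect_equal(cronbach_alpha(cbind(z, z, z, z)), 1)
  # independent items -> alpha near 0
  ind <- matrix(rnorm(4000 * 4), ncol = 4)
  expect_lt(abs(cronbach_alpha(ind)), 0.1)
  # invariances: item shifts and joint positive rescaling (standardized)
  m2 <- matrix(rnorm(50 * 3), ncol = 3)
  expect_equal(cronbach_alpha(m2),
               cronbach_alpha(sweep(m2, 2, c(5, -2, 0.3), "+")))
  expect_equal(cronbach_alpha(m2, standardize = TRUE),
               cronbach_alpha(m2 * 3.7, standardize = TRUE))
  expect_error(cronbach_alpha(matrix(1:10, ncol = 1)), "2 items")
  expect_warning(a <- cronbach_alpha(cbind(c(1, 1, 1), c(2, 2, 2))), "zero")
  expect_true(is.na(a))
})

test_that("partial correlation reduces, residualizes, and removes confounding", {
  set.seed(19)
  x <- rnorm(80); y <- 0.5 * x + rnorm(80)
  # no covariates -> plain Pearson, same p as cor.test
  pp <- partial_pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(pp$r, unname(ct$estimate))
  expect_equal(pp$p, ct$p.value)
  # y = x exactly
  expect_equal(partial_pearson(x, x)$r, 1)
  # two-route equality: adjusting inside equals correlating residuals
  z <- cbind(rnorm(80), rnorm(80))
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  expect_equal(partial_pearson(x, y, z)$r, partial_pearson(rx, ry)$r)
  # confounder-driven marginal correlation vanishes after adjustment
  zc <- rnorm(400)
  xc <- 2 * zc + rnorm(400); yc <- -1.5 * zc + rnorm(400)
  expect_gt(abs(partial_pearson(xc, yc)$r), 0.5)
  expect_lt(abs(partial_pearson(xc, yc, zc)$r), 0.15)
  expect_error(partial_pearson(x, y, cbind(z, z[, 1])), "collinear")
})

test_that("ANCOVA reduces to t-squared and removes covariate-driven differences", {
  set.seed(20)
  g <- rep(c("case", "control"), each = 25)
  v <- rnorm(50) + (g == "case") * 0.8
  a <- ancova_compare(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2)
  expect_equal(a$p, tt$p.value)
  expect_equal(sort(unname(a$adjusted_means)),
               sort(c(mean(v[g == "case"]), mean(v[g == "control"]))))
  # group difference entirely explained by the covariate
  z <- c(rnorm(25, 2), rnorm(25, 0))
  v2 <- 1.5 * z + rnorm(50, 0, 0.5)
  raw <- ancova_compare(v2, g)
  adj <- ancova_compare(v2, g, z)
  expect_lt(adj$p, 1)
  expect_gt(raw$F, 10)
  expect_lt(adj$F, 4)
})

test_that("baseline tables run t and chi-square tests per variable type", {
  set.seed(21)
  cohort <- data.frame(
    id = sprintf("p%03d", 1:200),
    group = rep(c("control", "case"), each = 100),
    age = c(rnorm(100, 74.4, 4.8), rnorm(100, 78.9, 4.8)),
    education_years = c(rnorm(100, 12.3, 4.4), rnorm(100, 9.3, 5.5)),
    mmse = c(rnorm(100, 27.5, 2.5), rnorm(100, 18.3, 5.2)),
    sex = rbinom(200, 1, 0.25),
    # published administration-order proportions: 29% vs 43% app-first
    app_first = c(rep(c(1, 0), c(29, 71)), rep(c(1, 0), c(43, 57))))
  tab <- baseline_compare(cohort, categorical = c("sex", "app_first"))
  expect_equal(nrow(tab), 5)
  expect_lt(tab$p[tab$variable == "age"], 0.001)
  expect_lt(tab$p[tab$variable == "app_first"], 0.05)
  # hand-computed pooled t on a 3+3 toy sample
  toy <- data.frame(group = rep(c("case", "control"), each = 3),
                    age = c(4, 5, 6, 1, 2, 3))
  row <- baseline_compare(toy, continuous = "age", categorical = character(0))
  sp <- sqrt((var(c(4, 5, 6)) + var(c(1, 2, 3))) / 2)
  expect_equal(abs(row$statistic), 3 / (sp * sqrt(2 / 3)))
  # identical groups: t = 0, p = 1
  same <- data.frame(group = rep(c("case", "control"), each = 3),
                     age = c(1, 2, 3, 1, 2, 3))
  expect_equal(baseline_compare(same, continuous = "age",
                                categorical = character(0))$p, 1)
})

test_that("test-retest reliability behaves across reliability regimes", {
  set.seed(22)
  n <- 60
  coh <- data.frame(id = seq_len(n), group = "case",
                    age = rnorm(n, 75, 5), education_years = rnorm(n, 10, 4))
  # identical administrations
  coh$tcvft_total_1 <- rnorm(n, 15, 4)
  coh$tcvft_total_2 <- coh$tcvft_total_1
  expect_equal(test_retest(coh, "tcvft_total")$r, 1)
  # independent administrations
  coh$tcvft_total_2 <- rnorm(n, 15, 4)
  expect_lt(abs(test_retest(coh, "tcvft_total")$r), 0.35)
  # rho = 0.8 at n = 20 lands inside the Fisher-z sampling band
  lat <- rnorm(20)
  c2 <- data.frame(id = 1:20, group = "case",
                   age = rnorm(20, 75, 5), education_years = rnorm(20, 10, 4))
  c2$tcvft_ws_1 <- sqrt(0.8) * lat + sqrt(0.2) * rnorm(20)
  c2$tcvft_ws_2 <- sqrt(0.8) * lat + sqrt(0.2) * rnorm(20)
  r <- test_retest(c2, "tcvft_ws")$r
  band <- tanh(atanh(0.8) + c(-1, 1) * 3 / sqrt(20 - 3))
  expect_gt(r, band[1]); expect_lt(r, band[2])
  # listwise exclusion is counted
  c2$tcvft_ws_2[1:3] <- NA
  expect_equal(test_retest(c2, "tcvft_ws")$n_excluded, 3)
})
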
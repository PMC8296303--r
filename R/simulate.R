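#' Group profile for the synthetic cohort generator
#'
#' Describes one arm (case or control) of a simulated validation cohort:
#' demographics, and the emission parameters of the word-production model.
#' Production follows an inhomogeneous Poisson clock whose rate decays
#' exponentially over the trial, `rate(t) = rate0 * exp(-rate_decay * t)`,
#' reflecting the sparse late retrieval characteristic of timed fluency.
#' Word identity follows a cluster-and-switch walk over the taxonomy: with
#' probability `p_perseveration` an earlier response is repeated, else
#' with probability `p_intrusion` a non-animal filler is emitted, else an
#' unused animal is drawn from the current subcategory with probability
#' `cluster_stay` (a switch to a fresh subcategory otherwise, and always
#' when the current subcategory is exhausted).
#'
#' @param n participants in the arm.
#' @param age_mean,age_sd age distribution in years (truncated at 60 from
#'   below: the screening population is 60+).
#' @param education_mean,education_sd education in years (truncated at 0).
#' @param male_fraction probability of male sex.
#' @param mmse_mean,mmse_sd MMSE points (truncated to `[0, 30]`, rounded).
#' @param rate0 initial production rate, words/s.
#' @param rate_decay rate decay constant, 1/s.
#' @param cluster_stay probability of staying in the current subcategory.
#' @param p_perseveration per-emission probability of repeating an earlier
#'   response.
#' @param p_intrusion per-emission probability of a non-animal filler.
#' @param retest_reliability target share of stable (person-level)
#'   variance in the log production rate across administrations, in
#'   `[0, 1]`.
#' @param between_sd SD of the person/administration log-rate offset.
#' @param age_slope,education_slope per-year effect of (centred) age and
#'   education on the log production rate, shared by both arms so adjusted
#'   analyses face real confounding.
#' @return A `group_profile` (named list).
#' @export
group_profile <- function(n, age_mean, age_sd, education_mean, education_sd,
                          male_fraction, mmse_mean, mmse_sd,
                          rate0, rate_decay, cluster_stay,
                          p_perseveration, p_intrusion,
                          retest_reliability = 0.8, between_sd = 0.2,
                          age_slope = -0.01, education_slope = 0.01) {
  p <- as.list(environment())
  stopifnot(n >= 1, age_sd >= 0, education_sd >= 0, mmse_sd >= 0,
            rate0 > 0, rate_decay >= 0,
            cluster_stay >= 0, cluster_stay <= 1,
            p_perseveration >= 0, p_perseveration <= 1,
            p_intrusion >= 0, p_intrusion <= 1,
            retest_reliability >= 0, retest_reliability <= 1,
            between_sd >= 0)
  structure(p, class = "group_profile")
}

#' Simulation configuration
#'
#' @param case,control `group_profile` objects.
#' @param seed integer seed; a fixed seed makes the generated cohort fully
#'   reproducible.
#' @param window task window in seconds.
#' @param taxonomy a `fluency_taxonomy`, or `NULL` for the bundled default.
#' @return A `sim_config` (named list).
#' @export
sim_config <- function(case, control, seed = 1L, window = 60,
                       taxonomy = NULL) {
  stopifnot(inherits(case, "group_profile"),
            inherits(control, "group_profile"))
  structure(list(case = case, control = control, seed = as.integer(seed),
                 window = window, taxonomy = taxonomy),
            class = "sim_config")
}

#' Default calibrated simulation profiles
#'
#' Arm profiles calibrated against the published validation cohort of the
#' instrument (100 early-AD cases vs 100 controls): demographics match the
#' reported group means/SDs, and the emission parameters were tuned,
#' offline and once, so that scored synthetic transcripts land near the
#' reported index-score profile -- mean totals near 7.7 (case) and 16.7
#' (control) with roughly 79% / 74% of correct words produced in the
#' first 30 s. Each constant's target is noted inline.
#'
#' @param n_case,n_control arm sizes (defaults 100/100, the validation
#'   design).
#' @param seed integer seed.
#' @return A `sim_config`.
#' @export
default_profiles <- function(n_case = 100L, n_control = 100L, seed = 1L) {
  control <- group_profile(
    n = n_control,
    age_mean = 74.4, age_sd = 4.8,        # control age 74.4 +/- 4.8 y
    education_mean = 12.3, education_sd = 4.4,  # education 12.3 +/- 4.4 y
    male_fraction = 0.25,                 # sex-matched, 25% male
    mmse_mean = 27.5, mmse_sd = 2.5,      # MMSE 27.5 +/- 2.5
    rate0 = 0.680,       # -> ~18.7 emissions/60 s (16.7 correct + errors)
    rate_decay = 0.0343, # -> 73.7% of production in the first 30 s
    cluster_stay = 0.50, # -> ~7.4 switches at 16.7 correct words
    p_perseveration = 0.053,  # -> ~1.0 perseverations per trial
    p_intrusion = 0.056,      # -> ~1.0 intrusions per trial
    retest_reliability = 0.8, # total-score retest target
    between_sd = 0.18)
  case <- group_profile(
    n = n_case,
    age_mean = 78.9, age_sd = 4.8,        # case age 78.9 +/- 4.8 y
    education_mean = 9.3, education_sd = 5.5,
    male_fraction = 0.25,
    mmse_mean = 18.3, mmse_sd = 5.2,
    rate0 = 0.440,       # -> ~9.2 emissions/60 s (7.7 correct + errors)
    rate_decay = 0.0445, # -> 79.2% of production in the first 30 s
    cluster_stay = 0.55, # -> ~2.6 switches at 7.7 correct words
    p_perseveration = 0.130,  # -> ~1.2 perseverations per trial
    p_intrusion = 0.038,      # -> ~0.3 intrusions per trial
    retest_reliability = 0.8,
    between_sd = 0.30)
  sim_config(case = case, control = control, seed = seed)
}

# Non-animal fillers used for simulated intrusions.
.filler_words <- c("table", "chair", "apple", "window", "car", "tree",
                   "house", "shoe", "banana", "spoon", "river", "phone",
                   "book", "flower", "cloud", "bread", "hat", "door",
                   "lamp", "pencil")

#' Generate one synthetic timed transcript
#'
#' Draws response onsets from the decaying-rate exponential clock of the
#' profile and response identities from its cluster-and-switch walk over
#' the taxonomy. Uses the current R random number stream; seed it (or use
#' [generate_cohort()]) for reproducibility.
#'
#' @param profile a `group_profile`.
#' @param tax a `fluency_taxonomy`.
#' @param ability additive offset on the log production rate (person and
#'   administration effects); 0 for a profile-average speaker.
#' @param participant_id,administration transcript metadata.
#' @param window trial duration in seconds.
#' @return A `fluency_transcript`.
#' @export
generate_transcript <- function(profile, tax, ability = 0,
                                participant_id = "sim",
                                administration = 1L, window = 60) {
  stopifnot(inherits(profile, "group_profile"),
            inherits(tax, "fluency_taxonomy"))
  # subcategory -> member tokens
  sub2tok <- list()
  for (can in names(tax$subcategories))
    for (sc in tax$subcategories[[can]])
      sub2tok[[sc]] <- c(sub2tok[[sc]], can)
  r0 <- profile$rate0 * exp(ability)
  lam <- profile$rate_decay
  used <- character(0)
  fillers_left <- .filler_words
  emitted <- character(0)
  onsets <- numeric(0)
  cur_sub <- NULL
  t <- 0
  repeat {
    # inversion of the cumulative rate: Lambda(t) = r0/lam * (1 - exp(-lam t))
    e <- stats::rexp(1)
    if (lam > 0) {
      arg <- exp(-lam * t) - lam * e / r0
      if (arg <= 0) break
      t_next <- -log(arg) / lam
    } else {
      t_next <- t + e / r0
    }
    if (t_next > window) break
    t <- t_next
    u <- stats::runif(1)
    if (length(emitted) > 0 && u < profile$p_perseveration) {
      tok <- sample(emitted, 1)
    } else if (stats::runif(1) < profile$p_intrusion) {
      if (length(fillers_left) == 0) fillers_left <- .filler_words
      tok <- sample(fillers_left, 1)
      fillers_left <- setdiff(fillers_left, tok)
    } else {
      avail_in <- if (is.null(cur_sub)) character(0)
                  else setdiff(sub2tok[[cur_sub]], used)
      if (length(avail_in) > 0 && stats::runif(1) < profile$cluster_stay) {
        tok <- if (length(avail_in) == 1) avail_in else sample(avail_in, 1)
      } else {
        # switch: fresh subcategory weighted by its unused member count
        counts <- vapply(sub2tok, function(v) length(setdiff(v, used)),
                         integer(1))
        if (!is.null(cur_sub)) counts[cur_sub] <- 0L
        if (all(counts == 0L)) break  # lexicon exhausted
        cur_sub <- sample(names(counts), 1, prob = counts)
        avail <- setdiff(sub2tok[[cur_sub]], used)
        tok <- if (length(avail) == 1) avail else sample(avail, 1)
      }
      used <- c(used, tok)
    }
    emitted <- c(emitted, tok)
    onsets <- c(onsets, t)
  }
  transcript(participant_id, emitted, onsets, duration = window,
             administration = administration)
}

.rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Generate a scored two-group synthetic cohort
#'
#' Draws demographics per arm (age truncated at 60, education at 0, MMSE
#' to `[0, 30]`), gives every participant a latent ability shared across
#' administrations and instruments, generates two administrations of the
#' app-based test plus one conventional administration, scores everything
#' with [compute_index_scores()], and computes the weighted-sum risk score
#' per administration. MMSE is coupled to the same latent ability so the
#' instruments correlate as they would in a real cohort.
#'
#' @param config a `sim_config`.
#' @param coeffs `coefficient_set` used for the WS columns.
#' @param retest generate a second administration (default `TRUE`, for all
#'   participants).
#' @return list with `cohort` (data.frame in the cohort-CSV layout),
#'   `transcripts` (list of `fluency_transcript`) and `truth` (the exact
#'   configuration and per-participant latent abilities).
#' @export
generate_cohort <- function(config,
                            coeffs = coefficient_preset(quiet = TRUE),
                            retest = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tax <- if (is.null(config$taxonomy)) default_taxonomy() else config$taxonomy
  window <- config$window
  # centring constants for the demographic coupling (pooled study means)
  age_c <- 76.6; edu_c <- 10.8
  all_rows <- list(); all_tr <- list(); latents <- list()
  for (arm in c("case", "control")) {
    pr <- config[[arm]]
    n <- pr$n
    age <- .rtrunc_norm(n, pr$age_mean, pr$age_sd, lower = 60)
    edu <- .rtrunc_norm(n, pr$education_mean, pr$education_sd, lower = 0)
    sex <- stats::rbinom(n, 1, pr$male_fraction)
    u <- stats::rnorm(n)  # latent ability, shared across administrations
    # MMSE partially loads on the same latent ability as production
    mmse <- round(pmin(30, pmax(0,
      pr$mmse_mean + pr$mmse_sd * (0.6 * u + sqrt(1 - 0.36) * stats::rnorm(n)))))
    rho <- pr$retest_reliability
    demo_shift <- pr$age_slope * (age - age_c) +
      pr$education_slope * (edu - edu_c)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", arm, i)
      admins <- if (retest) 1:2 else 1L
      scores <- list()
      for (a in admins) {
        abil <- pr$between_sd * (sqrt(rho) * u[i] +
                                   sqrt(1 - rho) * stats::rnorm(1)) +
          demo_shift[i]
        tr <- generate_transcript(pr, tax, ability = abil,
                                  participant_id = id, administration = a,
                                  window = window)
        all_tr[[length(all_tr) + 1L]] <- tr
        scores[[paste0("tcvft_", a)]] <-
          compute_index_scores(tr, tax, window = window)
      }
      abil_c <- pr$between_sd * (sqrt(rho) * u[i] +
                                   sqrt(1 - rho) * stats::rnorm(1)) +
        demo_shift[i]
      trc <- generate_transcript(pr, tax, ability = abil_c,
                                 participant_id = paste0(id, "_conv"),
                                 administration = 1L, window = window)
      all_tr[[length(all_tr) + 1L]] <- trc
      scores[["ccvft_1"]] <- compute_index_scores(trc, tax, window = window)
      demo <- list(age = age[i], education = edu[i], sex = sex[i])
      row <- list(id = id, group = arm, age = age[i],
                  education_years = edu[i], sex = sex[i], mmse = mmse[i])
      for (nm in names(scores)) {
        s <- scores[[nm]]
        pre <- sub("_([0-9]+)$", "", nm); adm <- sub("^.*_", "", nm)
        for (f in c("total", "first_half", "second_half", "perseveration",
                    "intrusion", "clustering", "switching"))
          row[[paste(pre, f, adm, sep = "_")]] <- s[[f]]
        row[[paste(pre, "ws", adm, sep = "_")]] <-
          weighted_sum(demo, s, coeffs)
      }
      rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
    all_rows[[arm]] <- do.call(rbind, rows)
    latents[[arm]] <- data.frame(id = sprintf("%s_%03d", arm, seq_len(n)),
                                 latent_ability = u)
  }
  cohort <- do.call(rbind, all_rows)
  rownames(cohort) <- NULL
  list(cohort = cohort,
       transcripts = all_tr,
       truth = list(config = config,
                    coefficient_preset = coeffs$preset,
                    latent = do.call(rbind, latents)))
}
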
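#' Construct a timed fluency transcript
#'
#' One administration of the timed category-fluency task for one
#' participant: an ordered list of raw spoken tokens with onset times in
#' seconds from task start.
#'
#' @param participant_id identifier (string or number).
#' @param tokens character vector of raw tokens in production order.
#' @param onsets numeric vector of onsets in seconds, nondecreasing, within
#'   `[0, duration]`; or `NULL` for an untimed transcript.
#' @param duration task duration in seconds (default 60).
#' @param administration administration index, 1 or 2 (2 = retest).
#' @return A `fluency_transcript` object.
#' @export
transcript <- function(participant_id, tokens, onsets = NULL,
                       duration = 60, administration = 1L) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be a single positive number")
  tokens <- as.character(tokens)
  n <- length(tokens)
  if (is.null(onsets)) onsets <- rep(NA_real_, n)
  onsets <- as.numeric(onsets)
  if (length(onsets) != n)
    stop("tokens and onsets must have equal length")
  timed <- !all(is.na(onsets))
  if (timed) {
    if (anyNA(onsets))
      stop("onsets must be all present or all missing")
    if (any(onsets < 0) || any(onsets > duration))
      stop("onsets must lie within [0, duration]")
    if (is.unsorted(onsets))
      stop("onsets must be nondecreasing")
  }
  structure(
    list(participant_id = participant_id,
         administration = as.integer(administration),
         duration = duration,
         responses = data.frame(position = seq_len(n) - 1L,
                                token = tokens, onset = onsets,
                                stringsAsFactors = FALSE)),
    class = "fluency_transcript")
}

#' @export
print.fluency_transcript <- function(x, ...) {
  cat("<fluency_transcript> participant ", as.character(x$participant_id),
      ", administration ", x$administration, ", ",
      nrow(x$responses), " responses / ", x$duration, " s\n", sep = "")
  invisible(x)
}

#' Label transcript responses as correct, perseveration or intrusion
#'
#' Each response receives exactly one label. A first occurrence of an
#' in-lexicon animal is `correct`; a first occurrence of an out-of-lexicon
#' token is an `intrusion`; any repetition of an earlier response --
#' correct or incorrect -- is a `perseveration`. Repeats are detected by
#' canonical token for in-lexicon responses (so a variant and its canonical
#' collide) and by case-folded raw token otherwise (so a repeated intrusion
#' counts as a perseveration).
#'
#' @param x a `fluency_transcript`.
#' @param tax a `fluency_taxonomy`.
#' @return data.frame with columns `position`, `token`, `onset`,
#'   `canonical` (`NA` for out-of-lexicon tokens) and `label`.
#' @export
label_responses <- function(x, tax) {
  stopifnot(inherits(x, "fluency_transcript"))
  r <- x$responses
  n <- nrow(r)
  canonical <- if (n) normalize_token(r$token, tax) else character(0)
  key <- ifelse(is.na(canonical), .norm_text(r$token), canonical)
  label <- character(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    if (key[i] %in% seen) {
      label[i] <- "perseveration"
    } else {
      label[i] <- if (is.na(canonical[i])) "intrusion" else "correct"
      seen <- c(seen, key[i])
    }
  }
  data.frame(position = r$position, token = r$token, onset = r$onset,
             canonical = canonical, label = label,
             stringsAsFactors = FALSE)
}

#' Segment correct responses into subcategory clusters
#'
#' A cluster is a maximal run of successively produced correct responses
#' sharing an animal subcategory; its size is its member count minus one.
#' By default the run is extended while the intersection of subcategory
#' sets over all its members stays non-empty (running-intersection
#' semantics); `chain_mode = "pairwise"` instead only requires each
#' adjacent pair to share a subcategory. Perseverations and intrusions are
#' skipped and do not interrupt a run unless `errors_break_clusters` is
#' set.
#'
#' @param labeled output of [label_responses()].
#' @param tax a `fluency_taxonomy`.
#' @param chain_mode `"intersection"` (default) or `"pairwise"`.
#' @param errors_break_clusters if `TRUE`, an intervening perseveration or
#'   intrusion terminates the current cluster.
#' @return data.frame, one row per cluster in production order, with
#'   columns `cluster`, `n_members`, `size` and list-columns
#'   `member_positions` and `shared_subcategories` (the intersection over
#'   members; possibly empty in pairwise mode).
#' @export
segment_clusters <- function(labeled, tax,
                             chain_mode = c("intersection", "pairwise"),
                             errors_break_clusters = FALSE) {
  chain_mode <- match.arg(chain_mode)
  stopifnot(inherits(tax, "fluency_taxonomy"))
  empty <- data.frame(cluster = integer(0), n_members = integer(0),
                      size = integer(0))
  empty$member_positions <- list()
  empty$shared_subcategories <- list()
  if (nrow(labeled) == 0L) return(empty)

  members <- list()      # positions of the open cluster
  inter <- NULL          # running intersection of the open cluster
  prev_sets <- NULL      # subcategory set of the previous member
  clusters <- list()
  close_cluster <- function() {
    if (length(members) == 0L) return()
    clusters[[length(clusters) + 1L]] <<-
      list(member_positions = unlist(members),
           shared_subcategories = sort(inter),
           n_members = length(members))
    members <<- list(); inter <<- NULL; prev_sets <<- NULL
  }
  for (i in seq_len(nrow(labeled))) {
    if (labeled$label[i] != "correct") {
      if (errors_break_clusters) close_cluster()
      next
    }
    sets <- tax$subcategories[[labeled$canonical[i]]]
    link <- if (chain_mode == "intersection") inter else prev_sets
    if (length(members) > 0L && length(intersect(link, sets)) > 0L) {
      members[[length(members) + 1L]] <- labeled$position[i]
      inter <- intersect(inter, sets)
    } else {
      close_cluster()
      members <- list(labeled$position[i])
      inter <- sets
    }
    prev_sets <- sets
  }
  close_cluster()
  if (length(clusters) == 0L) return(empty)
  out <- data.frame(cluster = seq_along(clusters),
                    n_members = vapply(clusters, `[[`, 1L, "n_members"))
  out$size <- out$n_members - 1L
  out$member_positions <- lapply(clusters, `[[`, "member_positions")
  out$shared_subcategories <- lapply(clusters, `[[`, "shared_subcategories")
  out
}

#' Compute the seven fluency index scores for one transcript
#'
#' Responses with onset beyond `window` are discarded, then the transcript
#' is labelled and segmented. The indices are: `total` (correct responses),
#' `first_half` (correct with onset strictly before `window/2`),
#' `second_half` (correct with onset at or after `window/2`),
#' `perseveration` and `intrusion` counts, `clustering` (mean cluster size,
#' 0 when there are no clusters), and `switching` (number of clusters minus
#' one, 0 when there are no clusters).
#'
#' For untimed transcripts (all onsets missing) the half scores are
#' unavailable (`NA`) unless `untimed_split = "midpoint"`, which splits the
#' correct responses at the midpoint of the response list by order index.
#'
#' @param x a `fluency_transcript`.
#' @param tax a `fluency_taxonomy`.
#' @param window scoring window in seconds (default 60; the 30-s variant of
#'   the instrument rescores the same transcript with `window = 30`).
#' @param untimed_split `"refuse"` (half scores `NA`) or `"midpoint"`.
#' @inheritParams segment_clusters
#' @return An `index_scores` object (named list) with the seven indices
#'   plus `window`.
#' @export
compute_index_scores <- function(x, tax, window = 60,
                                 chain_mode = c("intersection", "pairwise"),
                                 errors_break_clusters = FALSE,
                                 untimed_split = c("refuse", "midpoint")) {
  stopifnot(inherits(x, "fluency_transcript"))
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop("window must be a single positive number of seconds")
  untimed_split <- match.arg(untimed_split)
  timed <- nrow(x$responses) == 0L || !all(is.na(x$responses$onset))
  if (timed && nrow(x$responses)) {
    keep <- x$responses$onset <= window
    x$responses <- x$responses[keep, , drop = FALSE]
  }
  lab <- label_responses(x, tax)
  cl <- segment_clusters(lab, tax, chain_mode = chain_mode,
                         errors_break_clusters = errors_break_clusters)
  correct <- lab$label == "correct"
  total <- sum(correct)
  if (timed) {
    first_half <- sum(correct & lab$onset < window / 2)
    second_half <- sum(correct & lab$onset >= window / 2)
  } else if (untimed_split == "midpoint") {
    mid <- nrow(lab) / 2
    first_half <- sum(correct & seq_len(nrow(lab)) <= mid)
    second_half <- total - first_half
  } else {
    first_half <- NA_integer_
    second_half <- NA_integer_
  }
  structure(
    list(total = total,
         first_half = first_half,
         second_half = second_half,
         perseveration = sum(lab$label == "perseveration"),
         intrusion = sum(lab$label == "intrusion"),
         clustering = if (nrow(cl)) mean(cl$size) else 0,
         switching = if (nrow(cl)) nrow(cl) - 1L else 0L,
         window = window),
    class = "index_scores")
}

#' @export
print.index_scores <- function(x, ...) {
  cat("<index_scores> (window ", x$window, " s)\n", sep = "")
  v <- unlist(x[c("total", "first_half", "second_half", "perseveration",
                  "intrusion", "clustering", "switching")])
  print(round(v, 3))
  invisible(x)
}

#' Score a list of transcripts into a flat table
#'
#' @param transcripts list of `fluency_transcript` objects.
#' @param tax a `fluency_taxonomy`.
#' @param ... passed to [compute_index_scores()] (`window`, `chain_mode`,
#'   `errors_break_clusters`, `untimed_split`).
#' @return data.frame, one row per (participant, administration), with the
#'   identifier columns, the seven index scores and `window`.
#' @export
score_transcripts <- function(transcripts, tax, ...) {
  rows <- lapply(transcripts, function(tr) {
    s <- compute_index_scores(tr, tax, ...)
    data.frame(participant_id = as.character(tr$participant_id),
               administration = tr$administration,
               total = s$total, first_half = s$first_half,
               second_half = s$second_half,
               perseveration = s$perseveration, intrusion = s$intrusion,
               clustering = s$clustering, switching = s$switching,
               window = s$window, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Correct-response counts per time bin
#'
#' Splits the scoring window into equal-width bins and counts correct
#' responses per bin for each transcript. The resulting participants x
#' bins matrix is the default item set for internal-consistency
#' (Cronbach's alpha) analysis of the production process.
#'
#' @param transcripts list of timed `fluency_transcript` objects, one per
#'   participant.
#' @param tax a `fluency_taxonomy`.
#' @param width bin width in seconds (default 10).
#' @param window scoring window in seconds (default 60).
#' @return integer matrix, one row per transcript, one column per bin.
#' @export
time_bin_items <- function(transcripts, tax, width = 10, window = 60) {
  breaks <- seq(0, window, by = width)
  if (breaks[length(breaks)] < window) breaks <- c(breaks, window)
  m <- t(vapply(transcripts, function(tr) {
    lab <- label_responses(tr, tax)
    ons <- lab$onset[lab$label == "correct" & lab$onset <= window]
    if (anyNA(ons)) stop("time_bin_items requires timed transcripts")
    tab <- table(cut(ons, breaks, right = FALSE, include.lowest = TRUE))
    as.integer(tab)
  }, integer(length(breaks) - 1L)))
  rownames(m) <- vapply(transcripts, function(tr)
    as.character(tr$participant_id), character(1))
  m
}
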
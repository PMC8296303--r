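#' Read transcripts from CSV
#'
#' Expected columns: `participant_id`, `administration_index`, `position`,
#' `token`, `onset_s`; one row per response. Rows are grouped into one
#' transcript per (participant, administration) and ordered by `position`.
#' An optional `duration_s` column (constant within a transcript) overrides
#' the default 60-s duration.
#'
#' @param path CSV path.
#' @param duration default task duration in seconds when the file carries
#'   none.
#' @return list of `fluency_transcript` objects.
#' @export
read_transcripts_csv <- function(path, duration = 60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "administration_index", "position", "token",
            "onset_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("transcript CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  key <- paste(df$participant_id, df$administration_index, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    g <- g[order(g$position), , drop = FALSE]
    dur <- if ("duration_s" %in% names(g)) g$duration_s[1] else duration
    transcript(g$participant_id[1], g$token, g$onset_s,
               duration = dur, administration = g$administration_index[1])
  }) |> unname()
}

#' Write transcripts to CSV
#'
#' @param transcripts list of `fluency_transcript` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_csv <- function(transcripts, path) {
  if (length(transcripts) == 0L) {
    utils::write.csv(
      data.frame(participant_id = character(0),
                 administration_index = integer(0), position = integer(0),
                 token = character(0), onset_s = numeric(0),
                 duration_s = numeric(0)),
      path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(transcripts, function(tr) {
    r <- tr$responses
    data.frame(participant_id = as.character(tr$participant_id),
               administration_index = tr$administration,
               position = r$position, token = r$token, onset_s = r$onset,
               duration_s = tr$duration, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read transcripts from JSON lines
#'
#' One JSON object per line:
#' `{"participant_id": ..., "administration": int, "duration_s": num,
#'   "responses": [{"token": str, "onset_s": num}, ...]}`.
#'
#' @param path JSONL path.
#' @return list of `fluency_transcript` objects.
#' @export
read_transcripts_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    toks <- vapply(o$responses, function(r) as.character(r$token),
                   character(1))
    ons <- vapply(o$responses, function(r)
      if (is.null(r$onset_s)) NA_real_ else as.numeric(r$onset_s),
      numeric(1))
    transcript(o$participant_id, toks,
               if (all(is.na(ons))) NULL else ons,
               duration = if (is.null(o$duration_s)) 60 else o$duration_s,
               administration = if (is.null(o$administration)) 1L
                                else o$administration)
  })
}

#' Write transcripts to JSON lines
#'
#' @inheritParams write_transcripts_csv
#' @return `path`, invisibly.
#' @export
write_transcripts_jsonl <- function(transcripts, path) {
  lines <- vapply(transcripts, function(tr) {
    o <- list(participant_id = tr$participant_id,
              administration = tr$administration,
              duration_s = tr$duration,
              responses = lapply(seq_len(nrow(tr$responses)), function(i)
                list(token = tr$responses$token[i],
                     onset_s = tr$responses$onset[i])))
    jsonlite::toJSON(o, auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a scored cohort table
#'
#' The cohort CSV carries one row per participant: `id`, `group`
#' (`case`/`control`), `age`, `education_years`, `sex` (0 = female,
#' 1 = male), `mmse`, then score columns named
#' `<instrument>_<score>_<administration>` (e.g. `tcvft_ws_1`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("cohort ids must be unique")
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad))
    stop("group labels must be 'case'/'control'; found: ",
         paste(bad, collapse = ", "))
  df
}

#' @rdname read_cohort_csv
#' @param cohort cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
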
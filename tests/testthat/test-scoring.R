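test_that("response labelling handles repeats of correct and incorrect tokens", {
  tax <- pets_taxonomy()
  lab <- label_responses(timed_transcript(c("dog", "cat", "dog")), tax)
  expect_equal(lab$label, c("correct", "correct", "perseveration"))

  # repeats of an intrusion are perseverations ("correct or incorrect")
  lab <- label_responses(timed_transcript(c("dog", "table", "table")), tax)
  expect_equal(lab$label, c("correct", "intrusion", "perseveration"))

  # variant collapse: normalize first, then detect duplicates by canonical
  lab <- label_responses(timed_transcript(c("puppy", "dog")), tax)
  expect_equal(lab$canonical, c("dog", "dog"))
  expect_equal(lab$label, c("correct", "perseveration"))

  # case-folded raw matching for out-of-lexicon repeats
  lab <- label_responses(timed_transcript(c("Table", " table ")), tax)
  expect_equal(lab$label, c("intrusion", "perseveration"))
})

test_that("cluster segmentation follows the running-intersection rule", {
  tax <- pets_taxonomy()
  lab <- label_responses(timed_transcript(c("cow", "pig", "horse")), tax)
  cl <- segment_clusters(lab, tax)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 2)

  lab <- label_responses(
    timed_transcript(c("dog", "cat", "whale", "shark", "eagle")), tax)
  cl <- segment_clusters(lab, tax)
  expect_equal(cl$size, c(1, 1, 0))

  # empty input
  empty <- label_responses(timed_transcript(character(0), numeric(0)), tax)
  expect_equal(nrow(segment_clusters(empty, tax)), 0)

  # errors are skipped without breaking a cluster by default...
  lab <- label_responses(
    timed_transcript(c("cow", "table", "cow", "pig")), tax)
  cl <- segment_clusters(lab, tax)
  expect_equal(cl$n_members, 2)
  # ...but break it when asked to
  cl2 <- segment_clusters(lab, tax, errors_break_clusters = TRUE)
  expect_equal(cl2$n_members, c(1, 1))
})

test_that("running-intersection and pairwise chaining differ where they should", {
  tax <- toy_taxonomy()
  # a1 {A}, ab {A,B}, b1 {B}: pairwise chains all three, the running
  # intersection closes after ab (A ∩ {A,B} ∩ {B} is empty)
  lab <- label_responses(timed_transcript(c("a1", "ab", "b1")), tax)
  expect_equal(segment_clusters(lab, tax)$n_members, c(2, 1))
  expect_equal(segment_clusters(lab, tax, chain_mode = "pairwise")$n_members, 3)
})

test_that("index scores apply the window, halves and cluster summaries", {
  tax <- pets_taxonomy()
  tr <- timed_transcript(c("cow", "pig", "horse"), c(2, 5, 40))
  s <- compute_index_scores(tr, tax)
  expect_equal(s$total, 3)
  expect_equal(s$first_half, 2)
  expect_equal(s$second_half, 1)
  expect_equal(s$clustering, 2)
  expect_equal(s$switching, 0)
  expect_equal(s$perseveration, 0)
  expect_equal(s$intrusion, 0)

  # 30-s rescoring drops the late response and moves the half boundary
  s30 <- compute_index_scores(tr, tax, window = 30)
  expect_equal(s30$total, 2)
  expect_equal(s30$first_half, 2)  # onsets 2 and 5 are both before 15 s
  expect_equal(s30$second_half, 0)

  # half-open boundary: onset exactly window/2 goes to the second half
  sb <- compute_index_scores(timed_transcript(c("cow", "pig"), c(29, 30)), tax)
  expect_equal(sb$first_half, 1)
  expect_equal(sb$second_half, 1)

  # empty transcript scores all-zero
  s0 <- compute_index_scores(timed_transcript(character(0), numeric(0)), tax)
  expect_equal(unlist(s0[c("total", "first_half", "second_half",
                           "perseveration", "intrusion", "clustering",
                           "switching")]),
               c(total = 0, first_half = 0, second_half = 0,
                 perseveration = 0, intrusion = 0, clustering = 0,
                 switching = 0))

  expect_error(compute_index_scores(tr, tax, window = 0), "window")
})

test_that("untimed transcripts score counts but withhold half scores", {
  tax <- pets_taxonomy()
  tr <- transcript("u", c("cow", "pig", "dog", "cat"))
  s <- compute_index_scores(tr, tax)
  expect_equal(s$total, 4)
  expect_true(is.na(s$first_half))
  expect_error(weighted_sum(list(age = 70, education = 10, sex = 0), s),
               "first_half")
  s2 <- compute_index_scores(tr, tax, untimed_split = "midpoint")
  expect_equal(s2$first_half, 2)
  expect_equal(s2$second_half, 2)
})

test_that("score identities hold across random generated transcripts", {
  tax <- default_taxonomy()
  cfg <- default_profiles()
  set.seed(404)
  for (i in 1:25) {
    pr <- if (i %% 2) cfg$case else cfg$control
    tr <- generate_transcript(pr, tax, ability = stats::rnorm(1, 0, 0.3))
    s <- compute_index_scores(tr, tax)
    expect_equal(s$total, s$first_half + s$second_half)
    lab <- label_responses(tr, tax)
    cl <- segment_clusters(lab, tax)
    # every correct response sits in exactly one cluster
    expect_equal(sum(cl$size + 1), s$total)
    if (s$total >= 1) expect_equal(s$switching + 1, nrow(cl))
    positions <- sort(unlist(cl$member_positions))
    expect_equal(positions, lab$position[lab$label == "correct"])
  }
})

test_that("transcripts round-trip through CSV and JSONL", {
  tax <- pets_taxonomy()
  trs <- list(
    timed_transcript(c("dog", "cat", "table"), c(1.5, 3, 10), id = "p1"),
    timed_transcript(c("cow", "pig"), c(2, 59), id = "p2",
                     administration = 2))
  for (writer in list(write_transcripts_csv, write_transcripts_jsonl)) {
    reader <- if (identical(writer, write_transcripts_csv))
      read_transcripts_csv else read_transcripts_jsonl
    path <- withr::local_tempfile(fileext = ".dat")
    writer(trs, path)
    back <- reader(path)
    expect_length(back, 2)
    for (i in 1:2) {
      expect_equal(as.character(back[[i]]$participant_id),
                   as.character(trs[[i]]$participant_id))
      expect_equal(back[[i]]$administration, trs[[i]]$administration)
      expect_equal(back[[i]]$responses$token, trs[[i]]$responses$token)
      expect_equal(back[[i]]$responses$onset, trs[[i]]$responses$onset)
    }
  }
})

test_that("time-bin items partition the correct responses", {
  tax <- pets_taxonomy()
  trs <- list(timed_transcript(c("dog", "cat", "cow", "table"),
                               c(1, 12, 35, 50), id = "p1"),
              timed_transcript(c("pig", "horse"), c(5, 55), id = "p2"))
  m <- time_bin_items(trs, tax, width = 10, window = 60)
  expect_equal(dim(m), c(2, 6))
  expect_equal(rowSums(m), c(p1 = 3, p2 = 2))
  expect_equal(m["p1", ], c(1L, 1L, 0L, 1L, 0L, 0L),
               ignore_attr = TRUE)
})
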
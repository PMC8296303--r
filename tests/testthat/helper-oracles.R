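# Shared fixtures and independent oracles, built in code.

# Toy three-subcategory lexicon with single- and multi-membership tokens.
toy_taxonomy <- function() {
  taxonomy(list(
    list(canonical = "a1",  variants = list(), subcategories = list("A")),
    list(canonical = "b1",  variants = list(), subcategories = list("B")),
    list(canonical = "c1",  variants = list(), subcategories = list("C")),
    list(canonical = "ab",  variants = list(), subcategories = list("A", "B")),
    list(canonical = "bc",  variants = list(), subcategories = list("B", "C")),
    list(canonical = "abc", variants = list(),
         subcategories = list("A", "B", "C"))))
}

pets_taxonomy <- function() {
  taxonomy(list(
    list(canonical = "dog", variants = list("puppy"),
         subcategories = list("pets", "canines")),
    list(canonical = "cat", variants = list("kitten"),
         subcategories = list("pets", "felines")),
    list(canonical = "whale", variants = list(),
         subcategories = list("sea")),
    list(canonical = "shark", variants = list(),
         subcategories = list("sea")),
    list(canonical = "eagle", variants = list(),
         subcategories = list("birds")),
    list(canonical = "cow", variants = list(),
         subcategories = list("farm")),
    list(canonical = "pig", variants = list(),
         subcategories = list("farm")),
    list(canonical = "horse", variants = list(),
         subcategories = list("farm")),
    list(canonical = "bat", variants = list(),
         subcategories = list("flying", "mammals")),
    list(canonical = "seal", variants = list(),
         subcategories = list("sea", "mammals"))))
}

timed_transcript <- function(tokens, onsets = seq_along(tokens),
                             id = "p", duration = 60, administration = 1) {
  transcript(id, tokens, onsets, duration = duration,
             administration = administration)
}

# Brute-force cluster segmentation oracle: enumerate every contiguous
# partition of the correct-response sequence, keep partitions in which
# every run has a non-empty subcategory intersection, and select the
# greedy-maximal one (lexicographically longest run lengths from the
# left). Returns the vector of run lengths (member counts).
oracle_segment_sizes <- function(subcat_sets) {
  k <- length(subcat_sets)
  if (k == 0) return(integer(0))
  if (k == 1) return(1L)
  best <- NULL
  for (mask in 0:(2^(k - 1) - 1)) {
    breaks <- which(bitwAnd(mask, 2^(0:(k - 2))) > 0)
    bounds <- c(0, breaks, k)
    lens <- diff(bounds)
    ok <- TRUE
    start <- 1
    for (L in lens) {
      run <- subcat_sets[start:(start + L - 1)]
      if (length(Reduce(intersect, run)) == 0) { ok <- FALSE; break }
      start <- start + L
    }
    if (!ok) next
    if (is.null(best)) best <- lens
    else {
      n <- max(length(best), length(lens))
      a <- c(lens, rep(-1L, n - length(lens)))
      b <- c(best, rep(-1L, n - length(best)))
      cmpi <- which(a != b)[1]
      if (!is.na(cmpi) && a[cmpi] > b[cmpi]) best <- lens
    }
  }
  best
}

# All injective token sequences of length 1..length(tokens).
all_injective_sequences <- function(tokens) {
  out <- list()
  recurse <- function(prefix, remaining) {
    for (t in remaining) {
      seqv <- c(prefix, t)
      out[[length(out) + 1L]] <<- seqv
      recurse(seqv, setdiff(remaining, t))
    }
  }
  recurse(character(0), tokens)
  out
}

# All-pairs concordance AUC oracle: (#case>control + 0.5 * #ties) / (m*n).
oracle_auc <- function(scores, labels) {
  x <- scores[labels == "case"]
  y <- scores[labels == "control"]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive Youden search oracle: direct counting at every candidate
# threshold (midpoints between distinct scores plus infinities).
oracle_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  x <- scores[labels == "case"]; y <- scores[labels == "control"]
  se <- vapply(thr, function(t) mean(x >= t), numeric(1))
  sp <- vapply(thr, function(t) mean(y < t), numeric(1))
  j <- se + sp - 1
  o <- order(-j, -se, thr)
  list(j = j[o[1]], cutoff = thr[o[1]], sensitivity = se[o[1]],
       specificity = sp[o[1]])
}

# Hand logistic for closed-form checks.
oracle_logistic <- function(x) 1 / (1 + exp(-x))
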
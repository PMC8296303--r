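#' Animal lexicon with subcategory membership
#'
#' A taxonomy maps spoken-word tokens (canonicals plus their accepted
#' variants) to sets of semantic subcategories. Cluster and switch scoring
#' of a fluency transcript is driven entirely by this structure, so any
#' category or language can be substituted by supplying a different file.
#'
#' @details
#' Internally a `fluency_taxonomy` holds three components:
#' \describe{
#'   \item{subcategories}{named list, canonical token -> character vector of
#'     subcategory identifiers (always non-empty).}
#'   \item{variant_map}{named character vector, variant token -> canonical.}
#'   \item{registry}{character vector of all subcategory identifiers.}
#' }
#' All tokens are stored case-folded and whitespace-trimmed; lookup is
#' case-insensitive.
#'
#' @name fluency_taxonomy
NULL

.norm_text <- function(x) tolower(trimws(x))

#' Build a taxonomy from a list of entries
#'
#' @param entries list of entries, each a list with elements `canonical`
#'   (string), `variants` (character vector, may be empty) and
#'   `subcategories` (non-empty character vector).
#' @return A `fluency_taxonomy` object.
#' @export
taxonomy <- function(entries) {
  canonicals <- character(0)
  subcats <- list()
  variant_map <- character(0)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (is.null(e$canonical) || !nzchar(.norm_text(e$canonical)[1]))
      stop("taxonomy entry ", i, " has no canonical token")
    can <- .norm_text(e$canonical)
    sc <- unique(.norm_text(unlist(e$subcategories)))
    if (length(sc) == 0L)
      stop("taxonomy entry '", can, "' has an empty subcategory set")
    if (can %in% canonicals)
      stop("duplicate canonical token in taxonomy: '", can, "'")
    canonicals <- c(canonicals, can)
    subcats[[can]] <- sc
    vars <- unique(.norm_text(unlist(e$variants)))
    vars <- vars[nzchar(vars)]
    for (v in vars) {
      if (!is.na(variant_map[v]) && variant_map[v] != can)
        stop("variant '", v, "' maps to two canonicals ('",
             variant_map[v], "' and '", can, "')")
      variant_map[v] <- can
    }
  }
  clash <- intersect(names(variant_map), canonicals)
  clash <- clash[variant_map[clash] != clash]
  if (length(clash))
    stop("token(s) listed both as canonical and as a variant of another ",
         "canonical: ", paste(clash, collapse = ", "))
  structure(
    list(subcategories = subcats,
         variant_map = variant_map,
         registry = sort(unique(unlist(subcats, use.names = FALSE)))),
    class = "fluency_taxonomy")
}

#' Load a taxonomy from a JSON file
#'
#' The file is a JSON array of objects
#' `{"canonical": str, "variants": [str], "subcategories": [str]}` (UTF-8).
#'
#' @param path path to the JSON file.
#' @return A `fluency_taxonomy`.
#' @seealso [write_taxonomy()], [default_taxonomy()]
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw)) stop("taxonomy file must be a JSON array of entries")
  taxonomy(raw)
}

#' Write a taxonomy to a JSON file
#'
#' @param tax a `fluency_taxonomy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "fluency_taxonomy"))
  cans <- names(tax$subcategories)
  entries <- lapply(cans, function(can) {
    vars <- names(tax$variant_map)[tax$variant_map == can]
    list(canonical = can,
         variants = as.list(sort(vars)),
         subcategories = as.list(tax$subcategories[[can]]))
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Bundled default animal taxonomy
#'
#' An English animal lexicon (175 canonical entries, 29 subcategories)
#' modelled on the subcategory norms commonly used to score semantic
#' fluency, with multi-membership (e.g. "dog" is both a pet and a canine)
#' and common variants (plurals, diminutives, near-synonyms).
#'
#' @return A `fluency_taxonomy`.
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "animal_taxonomy.json",
                            package = "fluencyscreen", mustWork = TRUE))
}

#' Normalize raw tokens to canonical lexicon entries
#'
#' Tokens are case-folded and trimmed, then matched against canonicals and
#' variants. Unmatched tokens (non-animals) return `NA`.
#'
#' @param raw character vector of raw tokens; must be non-empty after
#'   trimming.
#' @param tax a `fluency_taxonomy`.
#' @return character vector: canonical token, or `NA` where out of lexicon.
#' @export
normalize_token <- function(raw, tax) {
  stopifnot(inherits(tax, "fluency_taxonomy"))
  x <- .norm_text(raw)
  if (any(!nzchar(x) | is.na(x)))
    stop("empty or missing token(s) at position(s): ",
         paste(which(!nzchar(x) | is.na(x)), collapse = ", "))
  out <- ifelse(x %in% names(tax$subcategories), x,
                unname(tax$variant_map[x]))
  out
}

#' Do two canonical tokens share a subcategory?
#'
#' @param a,b canonical tokens (single strings).
#' @param tax a `fluency_taxonomy`.
#' @return `TRUE` iff the subcategory sets of `a` and `b` intersect.
#' @export
shares_subcategory <- function(a, b, tax) {
  stopifnot(inherits(tax, "fluency_taxonomy"))
  sa <- tax$subcategories[[.norm_text(a)]]
  sb <- tax$subcategories[[.norm_text(b)]]
  if (is.null(sa)) stop("not a canonical token: '", a, "'")
  if (is.null(sb)) stop("not a canonical token: '", b, "'")
  length(intersect(sa, sb)) > 0L
}

#' @export
print.fluency_taxonomy <- function(x, ...) {
  cat("<fluency_taxonomy> ", length(x$subcategories), " canonical entries, ",
      length(x$variant_map), " variants, ",
      length(x$registry), " subcategories\n", sep = "")
  invisible(x)
}
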
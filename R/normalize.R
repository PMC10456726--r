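#' Normalize a metadata string
#'
#' All vocabulary storage, lookup and matching happens on normalized strings,
#' so that the downstream promise of querying by plain string equality is well
#' defined. Normalization is deliberately minimal: lowercase, strip leading and
#' trailing whitespace, and collapse internal whitespace runs to a single
#' space. Punctuation is never touched -- it is significant in strain names
#' such as "balb/c" and in units such as "hours/day".
#'
#' @param s character vector of raw strings.
#' @return character vector of the same length, normalized. Empty strings map
#'   to empty strings.
#' @examples
#' normalizeString("  Mus   Musculus ")  # "mus musculus"
#' normalizeString("OZONE")              # "ozone"
#' @export
normalizeString <- function(s) {
  if (length(s) == 0L) return(character(0))
  s <- as.character(s)
  s <- tolower(s)
  s <- gsub("[[:space:]]+", " ", s)
  s <- trimws(s)
  s
}

# internal guard: vocabularies reject empty strings everywhere
assertNonEmptyTerm <- function(s, what = "term") {
  if (length(s) != 1L || is.na(s) || !nzchar(s)) {
    stop(sprintf("%s must be a single non-empty string", what), call. = FALSE)
  }
  invisible(s)
}
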
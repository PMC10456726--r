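#' @import methods
#' @importFrom Matrix sparseMatrix rowSums t
#' @importClassesFrom Matrix Matrix
NULL

setClassUnion("dfOrNull", c("data.frame", "NULL"))

#' CategorySpec: one metadata category
#'
#' A metadata category (a column of the submission matrix) with its grouping
#' and value class. \code{controlled} categories carry a vocabulary and are
#' curated; \code{numeric} categories hold per-sample magnitudes (mass, age,
#' dose, ...) and are validated but never curated; \code{freetext} categories
#' (sampleLabel, inclusion, exclusion, comment) pass through untouched.
#'
#' @slot name single identifier string, unique across a store.
#' @slot grouping one of CoreSampleType, SampleDescription, StudyFactors,
#'   TimeSeries, Other.
#' @slot valueClass one of controlled, numeric, freetext.
#' @export
setClass("CategorySpec",
  representation(name = "character", grouping = "character",
                 valueClass = "character"))

categoryGroupings <- c("CoreSampleType", "SampleDescription", "StudyFactors",
                       "TimeSeries", "Other")
categoryValueClasses <- c("controlled", "numeric", "freetext")

setValidity("CategorySpec", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@grouping) != 1L ||
      !object@grouping %in% categoryGroupings)
    msg <- c(msg, sprintf("grouping must be one of %s",
                          paste(categoryGroupings, collapse = ", ")))
  if (length(object@valueClass) != 1L ||
      !object@valueClass %in% categoryValueClasses)
    msg <- c(msg, sprintf("valueClass must be one of %s",
                          paste(categoryValueClasses, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Vocabulary: the controlled term set of one category
#'
#' Main terms are the canonical strings; synonyms map many-to-one onto main
#' terms. All stored strings are normalized (see \code{\link{normalizeString}}).
#' The version integer increases on every mutation; fitted matching models are
#' keyed by it.
#'
#' @slot category the \linkS4class{CategorySpec} this vocabulary belongs to
#'   (always \code{valueClass == "controlled"}).
#' @slot mainTerms character vector of distinct normalized main terms.
#' @slot synonymMap named character vector: names are normalized synonym
#'   surfaces, values are the main terms they map to.
#' @slot version monotonically increasing integer.
#' @export
setClass("Vocabulary",
  representation(category = "CategorySpec", mainTerms = "character",
                 synonymMap = "character", version = "integer"))

setValidity("Vocabulary", function(object) {
  msg <- character(0)
  if (object@category@valueClass != "controlled")
    msg <- c(msg, "a Vocabulary requires a controlled category")
  mt <- object@mainTerms
  if (anyDuplicated(mt))
    msg <- c(msg, "mainTerms must be distinct")
  if (length(mt) && !identical(mt, normalizeString(mt)))
    msg <- c(msg, "mainTerms must be in normalized form")
  if (any(!nzchar(mt)))
    msg <- c(msg, "mainTerms may not contain empty strings")
  sm <- object@synonymMap
  if (length(sm)) {
    keys <- names(sm)
    if (is.null(keys) || any(!nzchar(keys)))
      msg <- c(msg, "synonymMap must be a named vector with non-empty names")
    else {
      if (anyDuplicated(keys))
        msg <- c(msg, "each synonym key maps to exactly one main term")
      if (!identical(keys, normalizeString(keys)))
        msg <- c(msg, "synonym keys must be in normalized form")
      if (any(keys %in% mt))
        msg <- c(msg, "a synonym may not shadow a main term of its category")
      if (!all(sm %in% mt))
        msg <- c(msg, "every synonym must map to an existing main term")
    }
  }
  if (length(object@version) != 1L || is.na(object@version) ||
      object@version < 1L)
    msg <- c(msg, "version must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' VocabularyStore: all categories of a deployment
#'
#' Holds the \linkS4class{CategorySpec}s of every registered category and one
#' \linkS4class{Vocabulary} per controlled category. The store-level invariant
#' is orthogonality: main-term sets of distinct controlled categories are
#' pairwise disjoint, so a standardized term identifies its category.
#' (Synonyms may collide across categories; only main terms are orthogonal.)
#'
#' @slot categories named list of \linkS4class{CategorySpec}, keyed by name.
#' @slot vocabularies named list of \linkS4class{Vocabulary}, one entry per
#'   controlled category.
#' @export
setClass("VocabularyStore",
  representation(categories = "list", vocabularies = "list"))

setValidity("VocabularyStore", function(object) {
  msg <- character(0)
  cats <- object@categories
  if (length(cats)) {
    if (is.null(names(cats)) || anyDuplicated(names(cats)))
      msg <- c(msg, "category names must be unique")
    ok <- vapply(cats, is, logical(1), "CategorySpec")
    if (!all(ok)) msg <- c(msg, "categories must be CategorySpec objects")
    else if (!identical(names(cats), unname(
               vapply(cats, function(x) x@name, character(1)))))
      msg <- c(msg, "category list names must match the specs' names")
  }
  vocabs <- object@vocabularies
  controlled <- names(cats)[vapply(cats, function(x)
    x@valueClass == "controlled", logical(1))]
  if (!setequal(names(vocabs), controlled))
    msg <- c(msg,
      "a category has a vocabulary if and only if it is controlled")
  viol <- storeViolations(object)
  if (nrow(viol)) {
    msg <- c(msg, sprintf("store invariant violated: %s",
                          paste(viol$message, collapse = "; ")))
  }
  if (length(msg)) msg else TRUE
})

#' TrigramModel: fitted character-trigram tf-idf space
#'
#' The vector-space model over all vocabulary surfaces (main terms and
#' synonyms alike -- each synonym is its own row, mapped to its main term).
#' Dimensions are the union of the character trigrams of all surfaces; rows
#' are tf-idf weighted and L2-normalized.
#'
#' @slot n gram length (default-locked at 3).
#' @slot componentIndex named integer: trigram -> column index.
#' @slot idf numeric, one smoothed inverse-document-frequency weight per
#'   component.
#' @slot surfaceMatrix sparse surfaces x components matrix of weighted unit
#'   row vectors.
#' @slot surfaces character vector of the normalized surface strings.
#' @slot mapsTo character: the main term each surface resolves to.
#' @slot category character: the category of each surface's vocabulary.
#' @slot vocabVersion named integer: the Vocabulary version(s) the model was
#'   fitted on; queries are refused when these drift from the store.
#' @export
setClass("TrigramModel",
  representation(n = "integer", componentIndex = "integer", idf = "numeric",
                 surfaceMatrix = "Matrix", surfaces = "character",
                 mapsTo = "character", category = "character",
                 vocabVersion = "integer"))

setValidity("TrigramModel", function(object) {
  msg <- character(0)
  if (length(object@n) != 1L || object@n < 1L)
    msg <- c(msg, "n must be a positive integer")
  if (length(object@idf) != length(object@componentIndex))
    msg <- c(msg, "idf must have one weight per component")
  nr <- length(object@surfaces)
  if (nrow(object@surfaceMatrix) != nr ||
      length(object@mapsTo) != nr || length(object@category) != nr)
    msg <- c(msg, "surfaces, mapsTo, category and matrix rows must align")
  if (ncol(object@surfaceMatrix) != length(object@componentIndex))
    msg <- c(msg, "matrix columns must match the component index")
  if (nr > 0) {
    norms <- sqrt(Matrix::rowSums(object@surfaceMatrix^2))
    if (any(abs(norms - 1) > 1e-8 & norms > 1e-12))
      msg <- c(msg, "row vectors must be unit length (or zero)")
  }
  if (length(msg)) msg else TRUE
})

#' MatchResult: ranked candidates for one query string
#'
#' @slot query the raw query string.
#' @slot candidates data.frame with columns \code{term} (main term),
#'   \code{surface} (the vocabulary surface that matched) and
#'   \code{similarity} (cosine in [0, 1]), sorted by similarity descending
#'   with deterministic tie-breaks.
#' @slot decision "auto" (exact hit or similarity at/above the accept
#'   threshold), "proposed" (needs confirmation) or "unmatched".
#' @export
setClass("MatchResult",
  representation(query = "character", candidates = "data.frame",
                 decision = "character"))

setValidity("MatchResult", function(object) {
  msg <- character(0)
  if (!object@decision %in% c("auto", "proposed", "unmatched"))
    msg <- c(msg, "decision must be auto, proposed or unmatched")
  cand <- object@candidates
  need <- c("term", "surface", "similarity")
  if (!all(need %in% names(cand)))
    msg <- c(msg, "candidates need columns term, surface, similarity")
  else if (nrow(cand)) {
    if (any(cand$similarity < -1e-12 | cand$similarity > 1 + 1e-12))
      msg <- c(msg, "similarities must lie in [0, 1]")
    if (is.unsorted(rev(cand$similarity), strictly = FALSE) &&
        any(diff(cand$similarity) > 1e-12))
      msg <- c(msg, "candidates must be sorted by similarity descending")
  }
  if (length(msg)) msg else TRUE
})

#' OntologyGraph: a parsed ontology dump
#'
#' A rooted, acyclic multi-parent graph of ontology nodes, as parsed from a
#' taxdump-style (ranked taxonomy) or tree-number-style (heading-prefixed
#' descriptor) dump. Node names and synonyms are kept raw here; normalization
#' happens when a vocabulary is built.
#'
#' @slot nodes data.frame with columns \code{id}, \code{name}, \code{rank}
#'   (NA when the dialect has no ranks).
#' @slot synonyms named list: id -> character vector of synonym surfaces.
#' @slot headings named list: id -> character vector of tree numbers (empty
#'   for taxdump dialect).
#' @slot parents named list: id -> character vector of parent ids.
#' @export
setClass("OntologyGraph",
  representation(nodes = "data.frame", synonyms = "list",
                 headings = "list", parents = "list"))

setValidity("OntologyGraph", function(object) {
  msg <- character(0)
  need <- c("id", "name", "rank")
  if (!all(need %in% names(object@nodes)))
    return("nodes needs columns id, name, rank")
  ids <- object@nodes$id
  if (anyDuplicated(ids)) msg <- c(msg, "node ids must be unique")
  for (slotName in c("synonyms", "headings", "parents")) {
    keys <- names(slot(object, slotName))
    if (length(keys) && !all(keys %in% ids))
      msg <- c(msg, sprintf("%s refers to unknown node ids", slotName))
  }
  allParents <- unique(unlist(object@parents, use.names = FALSE))
  if (length(allParents) && !all(allParents %in% ids))
    msg <- c(msg, "every referenced parent id must exist")
  else if (graphHasCycle(object@parents, ids))
    msg <- c(msg, "graph must be acyclic")
  if (length(msg)) msg else TRUE
})

# Kahn-style cycle detection on the parent map.
graphHasCycle <- function(parents, ids) {
  indeg <- integer(length(ids))
  names(indeg) <- ids
  for (ps in parents) for (p in ps) indeg[[p]] <- indeg[[p]] + 1L
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (p in parents[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  seen < length(ids)
}

#' ExtractionSpec: subtree roots plus a closed set of exclusion rules
#'
#' @slot includeRoots character vector of node ids or heading prefixes.
#' @slot exclusions list of rules built with \code{\link{dropRank}} and
#'   friends; free-form predicates are not representable.
#' @export
setClass("ExtractionSpec",
  representation(includeRoots = "character", exclusions = "list"))

exclusionRuleTypes <- c("drop_rank", "drop_descendants_of_name_containing",
                        "drop_rank_name_containing",
                        "drop_rank_name_matching_digits",
                        "subtract_reference")

setValidity("ExtractionSpec", function(object) {
  msg <- character(0)
  if (!length(object@includeRoots))
    msg <- c(msg, "at least one include root is required")
  for (rule in object@exclusions) {
    if (!is.list(rule) || is.null(rule$type) ||
        !rule$type %in% exclusionRuleTypes)
      msg <- c(msg, "exclusions must come from the closed rule set")
  }
  if (length(msg)) msg else TRUE
})

#' SubmissionMatrix: a sample-metadata matrix
#'
#' Rows are samples, columns are metadata categories, cells are strings
#' (freetext before standardization, main terms after). Multi-value cells use
#' ";" as the delimiter. Exactly one column is sampleLabel, required and
#' non-empty for every row.
#'
#' @slot categories named list of \linkS4class{CategorySpec} in column order.
#' @slot data data.frame of character columns, one per category.
#' @export
setClass("SubmissionMatrix",
  representation(categories = "list", data = "data.frame"))

setValidity("SubmissionMatrix", function(object) {
  msg <- character(0)
  catNames <- names(object@categories)
  if (anyDuplicated(catNames)) msg <- c(msg, "duplicate categories")
  if (sum(catNames == "sampleLabel") != 1L)
    msg <- c(msg, "exactly one sampleLabel category is required")
  if (!identical(catNames, colnames(object@data)))
    msg <- c(msg, "data columns must align with the category list")
  else if (nrow(object@data)) {
    if (!all(vapply(object@data, is.character, logical(1))))
      msg <- c(msg, "all cells must be character")
    else if (any(!nzchar(object@data[["sampleLabel"]])))
      msg <- c(msg, "sampleLabel must be non-empty for every row")
  }
  if (length(msg)) msg else TRUE
})

#' CurationReport: per-value record of the standardization passes
#'
#' One entry per delimited value of every non-empty cell, plus one per empty
#' cell, recording the original string, which pass resolved it, the final
#' string, and (for matcher passes) the cosine similarity.
#'
#' @slot entries data.frame with columns \code{row}, \code{category},
#'   \code{valueIndex}, \code{original}, \code{pass}, \code{final},
#'   \code{similarity}.
#' @export
setClass("CurationReport", representation(entries = "data.frame"))

curationPasses <- c("exact", "synonym", "nn_auto", "nn_confirmed",
                    "substring", "new_term", "passthrough", "empty")

setValidity("CurationReport", function(object) {
  need <- c("row", "category", "valueIndex", "original", "pass", "final",
            "similarity")
  if (!all(need %in% names(object@entries)))
    return(paste("entries needs columns", paste(need, collapse = ", ")))
  bad <- setdiff(unique(object@entries$pass), curationPasses)
  if (length(bad))
    return(sprintf("unknown pass labels: %s", paste(bad, collapse = ", ")))
  TRUE
})

#' ConfirmationSet: user decisions for values the first pass could not settle
#'
#' @slot proposals named character: key "category\\rORIGINAL" -> the accepted
#'   candidate main term (from the nearest-neighbor propose band or the
#'   substring pass).
#' @slot newTerms named character: key -> the final new-term string to adopt
#'   into the category's vocabulary (defaults to the original when built with
#'   \code{\link{confirmationSet}}).
#' @export
setClass("ConfirmationSet",
  representation(proposals = "character", newTerms = "character"))

setValidity("ConfirmationSet", function(object) {
  overlap <- intersect(names(object@proposals), names(object@newTerms))
  if (length(overlap))
    return("a value may be confirmed as a proposal or a new term, not both")
  TRUE
})

#' StoredStudy: one standardized submission held by a repository
#'
#' @slot id study identifier.
#' @slot author submitting author string.
#' @slot timestamp submission time (ISO 8601).
#' @slot matrix the standardized \linkS4class{SubmissionMatrix}.
#' @slot report the \linkS4class{CurationReport} of the standardization run.
#' @export
setClass("StoredStudy",
  representation(id = "character", author = "character",
                 timestamp = "character", matrix = "SubmissionMatrix",
                 report = "CurationReport"))

#' MetadataRepository: vocabularies, models and stored studies
#'
#' The programmatic access point: it owns the current
#' \linkS4class{VocabularyStore}, the fitted per-category
#' \linkS4class{TrigramModel}s, and the standardized studies, and answers
#' string-equality sample queries. All mutators return an updated repository.
#'
#' @slot store the vocabulary store.
#' @slot models named list of fitted models, one per controlled category.
#' @slot studies named list of \linkS4class{StoredStudy}.
#' @export
setClass("MetadataRepository",
  representation(store = "VocabularyStore", models = "list",
                 studies = "list"))

setMethod("show", "CategorySpec", function(object) {
  cat(sprintf("CategorySpec '%s' (%s, %s)\n", object@name, object@grouping,
              object@valueClass))
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary '%s': %d main terms, %d synonyms (version %d)\n",
              object@category@name, length(object@mainTerms),
              length(object@synonymMap), object@version))
})

setMethod("show", "VocabularyStore", function(object) {
  nTerms <- sum(vapply(object@vocabularies, function(v)
    length(v@mainTerms), integer(1)))
  cat(sprintf(
    "VocabularyStore: %d categories (%d controlled), %d main terms\n",
    length(object@categories), length(object@vocabularies), nTerms))
})

setMethod("show", "TrigramModel", function(object) {
  cat(sprintf(
    "TrigramModel (n = %d): %d surfaces x %d trigram components [%s]\n",
    object@n, length(object@surfaces), length(object@componentIndex),
    paste(unique(object@category), collapse = ", ")))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult '%s': %s", object@query, object@decision))
  if (nrow(object@candidates)) {
    cat(sprintf(" -> %s (%.3f)", object@candidates$term[1L],
                object@candidates$similarity[1L]))
  }
  cat("\n")
})

setMethod("show", "SubmissionMatrix", function(object) {
  cat(sprintf("SubmissionMatrix: %d samples x %d categories (%s)\n",
              nrow(object@data), length(object@categories),
              paste(utils::head(names(object@categories), 6), collapse = ", ")))
})

setMethod("show", "CurationReport", function(object) {
  tab <- table(object@entries$pass)
  cat(sprintf("CurationReport: %d entries (%s)\n", nrow(object@entries),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
})

setMethod("show", "MetadataRepository", function(object) {
  cat(sprintf("MetadataRepository: %d studies, %d controlled categories\n",
              length(object@studies), length(object@store@vocabularies)))
})
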
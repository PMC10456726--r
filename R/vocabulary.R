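#' Construct a Vocabulary
#'
#' Terms and synonyms are normalized on the way in (lowercase, whitespace
#' collapse) and deduplicated; synonyms that would shadow a main term of the
#' same category are an error here (use \code{\link{buildVocabulary}} for the
#' drop-and-log behaviour during ontology ingest).
#'
#' @param category a \linkS4class{CategorySpec} with
#'   \code{valueClass == "controlled"}, or a standard category name.
#' @param mainTerms character vector of main terms.
#' @param synonyms named character vector: synonym surface -> main term.
#' @param version starting version (default 1).
#' @return a \linkS4class{Vocabulary}.
#' @examples
#' v <- vocabulary("species", "mus musculus",
#'                 c(mouse = "mus musculus", mice = "mus musculus"))
#' @export
vocabulary <- function(category, mainTerms = character(),
                       synonyms = character(), version = 1L) {
  if (is.character(category)) category <- standardCategory(category)
  mainTerms <- unique(normalizeString(mainTerms))
  if (any(!nzchar(mainTerms)))
    stop("empty main terms are not allowed", call. = FALSE)
  syn <- character(0)
  if (length(synonyms)) {
    keys <- normalizeString(names(synonyms))
    vals <- normalizeString(unname(synonyms))
    if (any(!nzchar(keys)) || any(!nzchar(vals)))
      stop("empty synonyms are not allowed", call. = FALSE)
    keep <- !duplicated(keys)
    syn <- stats::setNames(vals[keep], keys[keep])
  }
  new("Vocabulary", category = category, mainTerms = mainTerms,
      synonymMap = syn, version = as.integer(version))
}

#' Vocabulary accessors
#' @param x a \linkS4class{Vocabulary}.
#' @return \code{mainTerms}: character vector of main terms;
#'   \code{synonymMap}: named character vector synonym -> main term;
#'   \code{vocabVersion}: integer version; \code{vocabCategory}: the
#'   \linkS4class{CategorySpec}.
#' @export
mainTerms <- function(x) x@mainTerms

#' @rdname mainTerms
#' @export
synonymMap <- function(x) x@synonymMap

#' @rdname mainTerms
#' @export
vocabVersion <- function(x) x@version

#' @rdname mainTerms
#' @export
vocabCategory <- function(x) x@category

# all lookup surfaces of a vocabulary: main terms plus synonym keys
vocabSurfaces <- function(x) c(x@mainTerms, names(x@synonymMap))

#' Construct a VocabularyStore
#'
#' @param vocabularies list of \linkS4class{Vocabulary} (or a single one).
#' @param categories named list of \linkS4class{CategorySpec} to register.
#'   Defaults to the categories of the given vocabularies plus sampleLabel.
#'   Controlled categories listed here without a vocabulary get an empty one.
#' @return a \linkS4class{VocabularyStore}.
#' @export
vocabularyStore <- function(vocabularies = list(), categories = NULL) {
  if (is(vocabularies, "Vocabulary")) vocabularies <- list(vocabularies)
  names(vocabularies) <- vapply(vocabularies, function(v)
    v@category@name, character(1))
  if (is.null(categories)) {
    categories <- lapply(vocabularies, function(v) v@category)
    if (!"sampleLabel" %in% names(categories))
      categories <- c(categories,
                      list(sampleLabel = standardCategory("sampleLabel")))
  }
  names(categories) <- vapply(categories, function(x) x@name, character(1))
  # ensure vocabulary categories are registered
  for (v in vocabularies) categories[[v@category@name]] <- v@category
  controlled <- names(categories)[vapply(categories, function(x)
    x@valueClass == "controlled", logical(1))]
  for (nm in setdiff(controlled, names(vocabularies)))
    vocabularies[[nm]] <- vocabulary(categories[[nm]])
  new("VocabularyStore", categories = categories,
      vocabularies = vocabularies[intersect(names(categories),
                                            names(vocabularies))])
}

#' VocabularyStore accessors
#' @param x a \linkS4class{VocabularyStore}.
#' @param category category name.
#' @return \code{getVocabulary}: the category's \linkS4class{Vocabulary};
#'   \code{storeCategories}: named list of all registered
#'   \linkS4class{CategorySpec}; \code{controlledCategories}: names of the
#'   controlled categories.
#' @export
getVocabulary <- function(x, category) {
  assertControlled(x, category)
  x@vocabularies[[category]]
}

#' @rdname getVocabulary
#' @export
storeCategories <- function(x) x@categories

#' @rdname getVocabulary
#' @export
controlledCategories <- function(x) names(x@vocabularies)

assertControlled <- function(store, category) {
  if (!category %in% names(store@categories))
    stop(sprintf("unknown category '%s'", category), call. = FALSE)
  if (store@categories[[category]]@valueClass != "controlled")
    stop(sprintf("category '%s' is not controlled", category), call. = FALSE)
  invisible(TRUE)
}

#' Look a string up in one category's vocabulary
#'
#' The lookup is a pure function of the store, the category and the
#' normalized form of \code{s}: a main-term hit, a synonym hit carrying the
#' mapped main term, or a miss.
#'
#' @param store a \linkS4class{VocabularyStore}.
#' @param category a controlled category name.
#' @param s raw string (normalized internally).
#' @return list with \code{result} ("main", "synonym" or "miss") and
#'   \code{term} (the main term, or NA on a miss).
#' @examples
#' store <- vocabularyStore(vocabulary("species", "mus musculus",
#'                                     c(mouse = "mus musculus")))
#' vocabLookup(store, "species", "Mouse")$term  # "mus musculus"
#' @export
vocabLookup <- function(store, category, s) {
  assertControlled(store, category)
  v <- store@vocabularies[[category]]
  q <- normalizeString(s)
  if (q %in% v@mainTerms) return(list(result = "main", term = q))
  if (q %in% names(v@synonymMap))
    return(list(result = "synonym", term = unname(v@synonymMap[[q]])))
  list(result = "miss", term = NA_character_)
}

#' Add a main term to a category's vocabulary
#'
#' Adding an already-present term is a no-op (the version is unchanged).
#' Adding a term that is a main term of a DIFFERENT controlled category is an
#' orthogonality error: main-term sets must stay pairwise disjoint so a term
#' identifies its category.
#'
#' @param store a \linkS4class{VocabularyStore}.
#' @param category a controlled category name.
#' @param s the term to add (normalized internally; empty is an error).
#' @return the updated store (the category's vocabulary version is bumped).
#' @export
addMainTerm <- function(store, category, s) {
  assertControlled(store, category)
  s <- normalizeString(s)
  assertNonEmptyTerm(s)
  v <- store@vocabularies[[category]]
  if (s %in% v@mainTerms) return(store)
  for (other in names(store@vocabularies)) {
    if (other != category && s %in% store@vocabularies[[other]]@mainTerms)
      stop(sprintf(
        "orthogonality violation: '%s' is already a main term of '%s'",
        s, other), call. = FALSE)
  }
  # a synonym of the same category being promoted to main term would shadow
  # itself; drop the synonym entry
  syn <- v@synonymMap[names(v@synonymMap) != s]
  v@mainTerms <- c(v@mainTerms, s)
  v@synonymMap <- syn
  v@version <- v@version + 1L
  validObject(v)
  store@vocabularies[[category]] <- v
  store
}

#' Add a synonym to a category's vocabulary
#'
#' @param store a \linkS4class{VocabularyStore}.
#' @param category a controlled category name.
#' @param synonym the synonym surface (may not equal a main term of the same
#'   category -- that would be redundant).
#' @param main the main term it maps to (must already exist).
#' @return the updated store.
#' @export
addSynonym <- function(store, category, synonym, main) {
  assertControlled(store, category)
  synonym <- normalizeString(synonym)
  main <- normalizeString(main)
  assertNonEmptyTerm(synonym, "synonym")
  assertNonEmptyTerm(main, "main term")
  v <- store@vocabularies[[category]]
  if (!main %in% v@mainTerms)
    stop(sprintf("'%s' is not a main term of '%s'", main, category),
         call. = FALSE)
  if (synonym %in% v@mainTerms)
    stop(sprintf(
      "redundancy: '%s' is already a main term of '%s'", synonym, category),
      call. = FALSE)
  if (synonym %in% names(v@synonymMap)) {
    if (identical(unname(v@synonymMap[[synonym]]), main)) return(store)
    stop(sprintf("'%s' already maps to '%s' in '%s'", synonym,
                 v@synonymMap[[synonym]], category), call. = FALSE)
  }
  v@synonymMap[[synonym]] <- main
  v@version <- v@version + 1L
  validObject(v)
  store@vocabularies[[category]] <- v
  store
}

# Violation scan shared by validateStore() and the class validity method
# (kept validity-free so the two cannot recurse).
storeViolations <- function(store) {
  out <- list()
  add <- function(type, categories, term, message)
    out[[length(out) + 1L]] <<- data.frame(
      type = type, categories = paste(categories, collapse = ","),
      term = term, message = message, stringsAsFactors = FALSE)
  vocabs <- store@vocabularies
  nms <- names(vocabs)
  if (length(nms) > 1L) {
    for (i in seq_len(length(nms) - 1L)) for (j in seq(i + 1L, length(nms))) {
      shared <- intersect(vocabs[[i]]@mainTerms, vocabs[[j]]@mainTerms)
      for (s in shared)
        add("orthogonality", c(nms[i], nms[j]), s,
            sprintf("'%s' is a main term of both '%s' and '%s'",
                    s, nms[i], nms[j]))
    }
  }
  for (nm in nms) {
    v <- vocabs[[nm]]
    dup <- unique(v@mainTerms[duplicated(v@mainTerms)])
    for (s in dup)
      add("redundancy", nm, s,
          sprintf("duplicate main term '%s' in '%s'", s, nm))
    shadow <- intersect(names(v@synonymMap), v@mainTerms)
    for (s in shadow)
      add("redundancy", nm, s,
          sprintf("synonym '%s' shadows a main term in '%s'", s, nm))
    dangling <- setdiff(unique(v@synonymMap), v@mainTerms)
    for (s in dangling)
      add("dangling", nm, s,
          sprintf("synonym target '%s' is not a main term of '%s'", s, nm))
  }
  if (!length(out))
    return(data.frame(type = character(), categories = character(),
                      term = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Validate a VocabularyStore
#'
#' Scans for every pairwise main-term overlap between controlled categories
#' and every intra-category redundancy (duplicate main terms, synonyms that
#' shadow a main term, dangling synonym targets).
#'
#' @param store a \linkS4class{VocabularyStore}.
#' @return data.frame of violations with columns \code{type},
#'   \code{categories}, \code{term}, \code{message}; zero rows means valid.
#' @export
validateStore <- function(store) storeViolations(store)
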
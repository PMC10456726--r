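#' Extract character n-grams from a string
#'
#' All length-\code{n} sliding windows over the full string, spaces included,
#' with multiplicity and no boundary padding: "mus musculus" yields ten
#' windows, among them "mus" (twice), "us ", "s m", " mu" and "usc". A
#' non-empty string shorter than \code{n} contributes itself as a single gram
#' so that one-letter units like "g" stay representable.
#'
#' @param s a normalized string.
#' @param n gram length (default 3).
#' @return character vector of grams in window order (empty for empty input).
#' @examples
#' extractNgrams("mus musculus")
#' @export
extractNgrams <- function(s, n = 3L) {
  len <- nchar(s)
  if (len == 0L) return(character(0))
  if (len < n) return(s)
  substring(s, 1:(len - n + 1L), n:len)
}

# named integer vector of gram counts
gramCounts <- function(s, n = 3L) {
  g <- extractNgrams(s, n)
  if (!length(g)) return(stats::setNames(integer(0), character(0)))
  tab <- table(g)
  stats::setNames(as.integer(tab), names(tab))
}

# Flatten a store / list of vocabularies / single vocabulary into the surface
# table the model is fitted on: main terms and synonyms are all first-class
# rows, each mapped to its main term.
surfaceTable <- function(x) {
  if (is(x, "VocabularyStore")) x <- x@vocabularies
  if (is(x, "Vocabulary")) x <- list(x)
  if (!length(x)) stop("at least one vocabulary is required", call. = FALSE)
  parts <- lapply(x, function(v) {
    data.frame(
      surface = c(v@mainTerms, names(v@synonymMap)),
      mapsTo = c(v@mainTerms, unname(v@synonymMap)),
      category = v@category@name,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  tab
}

storeVersions <- function(x) {
  if (is(x, "VocabularyStore")) x <- x@vocabularies
  if (is(x, "Vocabulary")) x <- list(x)
  vers <- vapply(x, function(v) v@version, integer(1), USE.NAMES = FALSE)
  stats::setNames(vers, vapply(x, function(v) v@category@name, character(1)))
}

# smoothed idf: never zero, stable under refit
idfWeight <- function(df, nDocs) log((1 + nDocs) / (1 + df)) + 1

#' Fit the trigram tf-idf model over vocabulary surfaces
#'
#' The vector-space components are the union of the character trigrams of all
#' surfaces (main terms and synonyms alike; each synonym is its own row,
#' mapped to its main term). Row weights are raw gram count times a smoothed
#' inverse document frequency, \code{ln((1 + D) / (1 + df)) + 1} over the
#' \code{D} surfaces, then L2-normalized. Adding a term to a vocabulary and
#' refitting extends the component space with that term's new grams.
#'
#' @param x a \linkS4class{VocabularyStore}, a list of
#'   \linkS4class{Vocabulary}, or a single vocabulary.
#' @param n gram length (default-locked at 3).
#' @return a \linkS4class{TrigramModel}.
#' @export
fitTrigramModel <- function(x, n = 3L) {
  tab <- surfaceTable(x)
  if (!nrow(tab)) stop("no surfaces to fit on", call. = FALSE)
  counts <- lapply(tab$surface, gramCounts, n = n)
  grams <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  componentIndex <- stats::setNames(seq_along(grams), grams)
  df <- integer(length(grams))
  names(df) <- grams
  for (ct in counts) df[names(ct)] <- df[names(ct)] + 1L
  idf <- idfWeight(df, nrow(tab))
  triplets <- do.call(rbind, lapply(seq_along(counts), function(i) {
    ct <- counts[[i]]
    w <- as.numeric(ct) * idf[names(ct)]
    w <- w / sqrt(sum(w^2))
    cbind(i = rep(i, length(ct)), j = componentIndex[names(ct)], x = w)
  }))
  mat <- Matrix::sparseMatrix(i = triplets[, "i"], j = triplets[, "j"],
                              x = triplets[, "x"],
                              dims = c(nrow(tab), length(grams)))
  new("TrigramModel", n = as.integer(n), componentIndex = componentIndex,
      idf = unname(idf), surfaceMatrix = mat, surfaces = tab$surface,
      mapsTo = tab$mapsTo, category = tab$category,
      vocabVersion = storeVersions(x))
}

#' Fit one model per controlled category of a store
#'
#' @param store a \linkS4class{VocabularyStore}.
#' @param n gram length.
#' @return named list of \linkS4class{TrigramModel}, one per controlled
#'   category with at least one surface; categories with empty vocabularies
#'   get no model (every query against them is unmatched).
#' @export
fitModels <- function(store, n = 3L) {
  out <- list()
  for (nm in names(store@vocabularies)) {
    v <- store@vocabularies[[nm]]
    if (length(v@mainTerms)) out[[nm]] <- fitTrigramModel(v, n = n)
  }
  out
}

#' Check that a model is current for a store
#'
#' @param model a \linkS4class{TrigramModel}.
#' @param store a \linkS4class{VocabularyStore}.
#' @return TRUE iff every vocabulary version the model was fitted on equals
#'   the store's current version for that category.
#' @export
modelCurrent <- function(model, store) {
  for (nm in names(model@vocabVersion)) {
    if (!nm %in% names(store@vocabularies)) return(FALSE)
    if (store@vocabularies[[nm]]@version != model@vocabVersion[[nm]])
      return(FALSE)
  }
  TRUE
}

#' Coerce a string into a fitted model's component space
#'
#' Grams absent from the model's components are dropped; the remaining counts
#' are idf-weighted and L2-normalized. A string sharing no gram with the
#' vocabulary maps to the zero vector.
#'
#' @param model a \linkS4class{TrigramModel}.
#' @param s a string (normalized internally).
#' @return numeric vector of length \code{length(componentIndex)}.
#' @export
vectorizeTerm <- function(model, s) {
  ct <- gramCounts(normalizeString(s), model@n)
  ct <- ct[names(ct) %in% names(model@componentIndex)]
  v <- numeric(length(model@componentIndex))
  if (length(ct)) {
    j <- model@componentIndex[names(ct)]
    v[j] <- as.numeric(ct) * model@idf[j]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
  }
  v
}

# Cosines are ranked on their value rounded to 12 decimals (then shorter
# surface, then lexicographic surface) so that mathematically tied scores
# computed in different summation orders break ties identically.
rankCandidates <- function(term, surface, similarity, k) {
  keep <- which(round(similarity, 12) > 0)  # no shared gram, no candidacy
  term <- term[keep]; surface <- surface[keep]
  similarity <- similarity[keep]
  ord <- order(-round(similarity, 12), nchar(surface), surface)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(term = term[ord], surface = surface[ord],
             similarity = similarity[ord], stringsAsFactors = FALSE)
}

matchDecision <- function(topSim, acceptThreshold, proposeThreshold) {
  if (round(topSim, 12) >= acceptThreshold) "auto"
  else if (round(topSim, 12) >= proposeThreshold) "proposed"
  else "unmatched"
}

emptyCandidates <- function()
  data.frame(term = character(), surface = character(),
             similarity = numeric(), stringsAsFactors = FALSE)

exactCandidate <- function(surfaces, mapsTo, q) {
  idx <- which(surfaces == q)
  # prefer a main-term row (surface == mapsTo) over a synonym row of the
  # same surface string; then first occurrence
  idx <- idx[order(surfaces[idx] != mapsTo[idx])][1L]
  data.frame(term = mapsTo[idx], surface = q, similarity = 1.0,
             stringsAsFactors = FALSE)
}

#' Nearest vocabulary terms for query strings
#'
#' The first-pass matcher: an exact main-term or synonym hit short-circuits
#' to \code{decision = "auto"} at similarity 1.0; otherwise the query is
#' coerced into the model space and the top-\code{k} surfaces by cosine
#' similarity are returned, each reporting the main term it maps to. The top
#' similarity decides: at or above \code{acceptThreshold} the match is
#' applied automatically, at or above \code{proposeThreshold} it is proposed
#' for confirmation, below it the query is unmatched. A query sharing no
#' gram with the vocabulary is unmatched with no candidates.
#'
#' @param model a \linkS4class{TrigramModel}.
#' @param s character vector of query strings.
#' @param k number of candidates to return (default 5).
#' @param acceptThreshold cosine at/above which a match is automatic
#'   (default 0.80).
#' @param proposeThreshold cosine at/above which a match is proposed
#'   (default 0.20).
#' @return a \linkS4class{MatchResult} for a single query, otherwise a list
#'   of them.
#' @export
nearestTerm <- function(model, s, k = 5L, acceptThreshold = 0.80,
                        proposeThreshold = 0.20) {
  stopifnot(k >= 1L)
  single <- length(s) == 1L
  out <- vector("list", length(s))
  for (qi in seq_along(s)) {
    raw <- s[[qi]]
    q <- normalizeString(raw)
    if (q %in% model@surfaces) {
      out[[qi]] <- new("MatchResult", query = raw,
                       candidates = exactCandidate(model@surfaces,
                                                   model@mapsTo, q),
                       decision = "auto")
      next
    }
    qvec <- vectorizeTerm(model, q)
    if (sum(qvec) == 0) {
      out[[qi]] <- new("MatchResult", query = raw,
                       candidates = emptyCandidates(),
                       decision = "unmatched")
      next
    }
    sims <- as.numeric(model@surfaceMatrix %*% qvec)
    sims <- pmin(pmax(sims, 0), 1)
    cand <- rankCandidates(model@mapsTo, model@surfaces, sims, k)
    out[[qi]] <- new("MatchResult", query = raw, candidates = cand,
                     decision = if (nrow(cand) == 0L) "unmatched"
                                else matchDecision(cand$similarity[1L],
                                                   acceptThreshold,
                                                   proposeThreshold))
  }
  if (single) out[[1L]] else out
}

#' MatchResult accessors
#' @param x a \linkS4class{MatchResult}.
#' @return \code{matchCandidates}: the ranked candidate data.frame;
#'   \code{matchDecisionOf}: "auto", "proposed" or "unmatched";
#'   \code{topTerm}: the top-ranked main term (NA when unmatched with no
#'   candidates).
#' @export
matchCandidates <- function(x) x@candidates

#' @rdname matchCandidates
#' @export
matchDecisionOf <- function(x) x@decision

#' @rdname matchCandidates
#' @export
topTerm <- function(x)
  if (nrow(x@candidates)) x@candidates$term[1L] else NA_character_

# independent sliding-window extraction for the brute-force path
bruteWindows <- function(s, n) {
  len <- nchar(s)
  if (len == 0L) return(character(0))
  if (len < n) return(s)
  vapply(seq_len(len - n + 1L), function(i) substr(s, i, i + n - 1L),
         character(1))
}

bruteCounts <- function(s, n) {
  w <- bruteWindows(s, n)
  out <- new.env(parent = emptyenv())
  for (g in w) {
    prev <- if (is.null(out[[g]])) 0L else out[[g]]
    out[[g]] <- prev + 1L
  }
  keys <- ls(out)
  stats::setNames(vapply(keys, function(kk) out[[kk]], integer(1)), keys)
}

#' Brute-force nearest neighbors (independent oracle)
#'
#' Same contract as \code{\link{nearestTerm}}, computed without the indexed
#' model: gram counts, document frequencies, idf weights and per-pair cosines
#' are all recomputed directly from the vocabularies with an independent code
#' path. Used to cross-check the model in the test suite; identical results
#' (top-1 term exactly, similarity to within numerical noise) are the
#' expectation, not a coincidence.
#'
#' @param vocabularies a \linkS4class{VocabularyStore}, list of
#'   \linkS4class{Vocabulary}, or single vocabulary.
#' @param s character vector of query strings.
#' @param k,acceptThreshold,proposeThreshold as in \code{\link{nearestTerm}}.
#' @param n gram length.
#' @return a \linkS4class{MatchResult}, or a list of them for vector input.
#' @export
bruteForceNearest <- function(vocabularies, s, k = 5L,
                              acceptThreshold = 0.80,
                              proposeThreshold = 0.20, n = 3L) {
  stopifnot(k >= 1L)
  tab <- surfaceTable(vocabularies)
  nDocs <- nrow(tab)
  surfCounts <- lapply(tab$surface, bruteCounts, n = n)
  dfEnv <- new.env(parent = emptyenv())
  for (ct in surfCounts) for (g in names(ct)) {
    prev <- if (is.null(dfEnv[[g]])) 0L else dfEnv[[g]]
    dfEnv[[g]] <- prev + 1L
  }
  idfOf <- function(g) log((1 + nDocs) / (1 + dfEnv[[g]])) + 1
  surfWeights <- lapply(surfCounts, function(ct) {
    w <- vapply(names(ct), function(g) ct[[g]] * idfOf(g), numeric(1))
    w / sqrt(sum(w^2))
  })
  single <- length(s) == 1L
  out <- vector("list", length(s))
  for (qi in seq_along(s)) {
    raw <- s[[qi]]
    q <- normalizeString(raw)
    if (q %in% tab$surface) {
      out[[qi]] <- new("MatchResult", query = raw,
                       candidates = exactCandidate(tab$surface, tab$mapsTo,
                                                   q),
                       decision = "auto")
      next
    }
    qct <- bruteCounts(q, n)
    known <- names(qct)[vapply(names(qct), function(g)
      !is.null(dfEnv[[g]]), logical(1))]
    if (!length(known)) {
      out[[qi]] <- new("MatchResult", query = raw,
                       candidates = emptyCandidates(),
                       decision = "unmatched")
      next
    }
    qw <- vapply(known, function(g) qct[[g]] * idfOf(g), numeric(1))
    qw <- qw / sqrt(sum(qw^2))
    sims <- vapply(surfWeights, function(sw) {
      shared <- intersect(names(sw), known)
      if (!length(shared)) return(0)
      sum(sw[shared] * qw[shared])
    }, numeric(1))
    sims <- pmin(pmax(sims, 0), 1)
    cand <- rankCandidates(tab$mapsTo, tab$surface, sims, k)
    out[[qi]] <- new("MatchResult", query = raw, candidates = cand,
                     decision = if (nrow(cand) == 0L) "unmatched"
                                else matchDecision(cand$similarity[1L],
                                                   acceptThreshold,
                                                   proposeThreshold))
  }
  if (single) out[[1L]] else out
}

#' Substring search over vocabulary surfaces (second pass)
#'
#' Finds surfaces (main terms or synonyms) where the normalized query is a
#' substring of the surface, or the surface is a substring of the query.
#' Hits are ranked by length ratio (shorter over longer, descending), then by
#' shorter surface, then lexicographically. Substring hits are only ever
#' proposed, never auto-applied.
#'
#' @param vocabularies a \linkS4class{VocabularyStore}, list of
#'   \linkS4class{Vocabulary}, or single vocabulary.
#' @param s a non-empty query string.
#' @return data.frame with columns \code{term}, \code{surface},
#'   \code{direction} ("query_in_surface", "surface_in_query" or "equal")
#'   and \code{ratio}.
#' @export
substringMatch <- function(vocabularies, s) {
  q <- normalizeString(s)
  if (!nzchar(q)) stop("empty query", call. = FALSE)
  tab <- surfaceTable(vocabularies)
  qIn <- vapply(tab$surface, function(sf) grepl(q, sf, fixed = TRUE),
                logical(1), USE.NAMES = FALSE)
  sIn <- vapply(tab$surface, function(sf) grepl(sf, q, fixed = TRUE),
                logical(1), USE.NAMES = FALSE)
  hit <- qIn | sIn
  if (!any(hit))
    return(data.frame(term = character(), surface = character(),
                      direction = character(), ratio = numeric(),
                      stringsAsFactors = FALSE))
  tab <- tab[hit, , drop = FALSE]
  qIn <- qIn[hit]; sIn <- sIn[hit]
  direction <- ifelse(qIn & sIn, "equal",
                      ifelse(qIn, "query_in_surface", "surface_in_query"))
  lens <- nchar(tab$surface)
  ratio <- pmin(lens, nchar(q)) / pmax(lens, nchar(q))
  ord <- order(-round(ratio, 12), lens, tab$surface)
  data.frame(term = tab$mapsTo[ord], surface = tab$surface[ord],
             direction = direction[ord], ratio = ratio[ord],
             stringsAsFactors = FALSE)
}

#' Serialize / restore a fitted model
#'
#' A single JSON file: a header (gram length, fitted vocabulary versions) and
#' the numeric payload (components, idf weights, surface rows and the sparse
#' weight matrix in triplet form). \code{loadModel} reconstructs the model;
#' serving queries against a store whose vocabulary versions have moved on is
#' refused via \code{\link{modelCurrent}}.
#'
#' @param model a \linkS4class{TrigramModel}.
#' @param path file path.
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: a
#'   \linkS4class{TrigramModel}.
#' @export
saveModel <- function(model, path) {
  trip <- Matrix::summary(model@surfaceMatrix)
  payload <- list(
    header = list(format = "metacurate-trigram-model", n = model@n,
                  vocab_version = as.list(model@vocabVersion)),
    components = names(model@componentIndex),
    idf = model@idf,
    surfaces = model@surfaces, maps_to = model@mapsTo,
    category = model@category,
    matrix = list(i = trip$i, j = trip$j, x = trip$x,
                  dims = dim(model@surfaceMatrix)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$header$format) ||
      p$header$format != "metacurate-trigram-model")
    stop("not a serialized trigram model: ", path, call. = FALSE)
  mat <- Matrix::sparseMatrix(i = p$matrix$i, j = p$matrix$j,
                              x = p$matrix$x, dims = p$matrix$dims)
  new("TrigramModel", n = as.integer(p$header$n),
      componentIndex = stats::setNames(seq_along(p$components),
                                       p$components),
      idf = as.numeric(p$idf), surfaceMatrix = mat,
      surfaces = p$surfaces, mapsTo = p$maps_to, category = p$category,
      vocabVersion = stats::setNames(
        as.integer(unlist(p$header$vocab_version)),
        names(p$header$vocab_version)))
}
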
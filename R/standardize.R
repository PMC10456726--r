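#' Build a ConfirmationSet
#'
#' User decisions for the values the automatic pass could not settle: either
#' accept a proposed candidate (from the nearest-neighbor propose band or the
#' substring pass), or adopt the value as a new vocabulary term. Keys are the
#' (category, original value) pair; the same decision applies wherever that
#' value recurs in the matrix.
#'
#' @param proposals named character of accepted proposals; use
#'   \code{confirmProposal} to build.
#' @param newTerms named character of accepted new terms; use
#'   \code{confirmNewTerm}.
#' @return a \linkS4class{ConfirmationSet}.
#' @export
confirmationSet <- function(proposals = character(),
                            newTerms = character()) {
  new("ConfirmationSet", proposals = proposals, newTerms = newTerms)
}

confirmationKey <- function(category, original)
  paste(category, normalizeString(original), sep = "\r")

#' @rdname confirmationSet
#' @param x a \linkS4class{ConfirmationSet}.
#' @param category category name.
#' @param original the original (freetext) value being confirmed.
#' @param term the accepted candidate main term.
#' @export
confirmProposal <- function(x, category, original, term) {
  x@proposals[[confirmationKey(category, original)]] <-
    normalizeString(term)
  validObject(x)
  x
}

#' @rdname confirmationSet
#' @param finalTerm the string to adopt as the new main term; defaults to the
#'   original value (the confirmation box is preloaded with the observed
#'   term, which the user may edit).
#' @export
confirmNewTerm <- function(x, category, original, finalTerm = original) {
  x@newTerms[[confirmationKey(category, original)]] <-
    normalizeString(finalTerm)
  validObject(x)
  x
}

#' Value class of a category
#'
#' Controlled categories are curated against their vocabulary; numeric
#' categories (per-sample magnitudes such as mass, age, dose or time) are
#' validated as numbers but never curated; freetext categories pass through.
#'
#' @param store a \linkS4class{VocabularyStore}.
#' @param category category name.
#' @return "controlled", "numeric" or "freetext".
#' @export
classifyCell <- function(store, category) {
  if (!category %in% names(store@categories))
    stop(sprintf("unknown category '%s'", category), call. = FALSE)
  store@categories[[category]]@valueClass
}

# decimal or scientific notation; locale comma decimals are rejected
isNumericValue <- function(s)
  grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)

splitCell <- function(cell) {
  if (!nzchar(cell)) return(character(0))
  trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
}

emptyWorkEntries <- function() {
  data.frame(row = integer(), category = character(),
             valueIndex = integer(), original = character(),
             pass = character(), final = character(),
             similarity = numeric(), status = character(),
             stringsAsFactors = FALSE)
}

#' First pass: exact, synonym and nearest-neighbor curation
#'
#' Walks every delimited value of every cell. Controlled values resolve as
#' \code{exact} (main-term hit), \code{synonym} (synonym hit, mapped), or
#' \code{nn_auto} (cosine at/above the accept threshold); values in the
#' propose band are queued for confirmation and values below it are left
#' unmatched. Numeric values must parse as numbers (decimal or scientific
#' notation) and pass through; freetext passes through; empty cells are
#' recorded as empty.
#'
#' @param x a \linkS4class{SubmissionMatrix}.
#' @param store a \linkS4class{VocabularyStore}.
#' @param models named list of \linkS4class{TrigramModel} per controlled
#'   category, fitted on the store's current versions (see
#'   \code{\link{fitModels}}).
#' @param acceptThreshold,proposeThreshold,k matcher settings, see
#'   \code{\link{nearestTerm}}.
#' @return internal working report: a data.frame of entries plus a
#'   \code{candidates} attribute; feed into \code{\link{pass2Substring}}.
#' @export
pass1Auto <- function(x, store, models, acceptThreshold = 0.80,
                      proposeThreshold = 0.20, k = 5L) {
  for (nm in names(models)) {
    if (!modelCurrent(models[[nm]], store))
      stop(sprintf(
        "model for '%s' is stale (vocabulary has moved on); retrain required",
        nm), call. = FALSE)
  }
  entries <- list()
  candidates <- list()
  df <- x@data
  for (ri in seq_len(nrow(df))) {
    for (cat in names(x@categories)) {
      cls <- classifyCell(store, cat)
      cell <- df[ri, cat]
      values <- splitCell(cell)
      if (!length(values)) {
        entries[[length(entries) + 1L]] <- data.frame(
          row = ri, category = cat, valueIndex = 1L, original = "",
          pass = "empty", final = "", similarity = NA_real_,
          status = "resolved", stringsAsFactors = FALSE)
        candidates[[length(entries)]] <- NULL
        next
      }
      for (vi in seq_along(values)) {
        val <- values[[vi]]
        entry <- data.frame(row = ri, category = cat, valueIndex = vi,
                            original = val, pass = NA_character_,
                            final = NA_character_, similarity = NA_real_,
                            status = "unmatched", stringsAsFactors = FALSE)
        cand <- NULL
        if (cls == "freetext") {
          entry$pass <- "passthrough"; entry$final <- val
          entry$status <- "resolved"
        } else if (cls == "numeric") {
          if (!isNumericValue(val))
            stop(sprintf(
              "row %d, category '%s': '%s' is not a valid number",
              ri, cat, val), call. = FALSE)
          entry$pass <- "passthrough"; entry$final <- val
          entry$status <- "resolved"
        } else {
          hit <- vocabLookup(store, cat, val)
          if (hit$result == "main") {
            entry$pass <- "exact"; entry$final <- hit$term
            entry$similarity <- 1.0; entry$status <- "resolved"
          } else if (hit$result == "synonym") {
            entry$pass <- "synonym"; entry$final <- hit$term
            entry$similarity <- 1.0; entry$status <- "resolved"
          } else if (is.null(models[[cat]])) {
            entry$status <- "unmatched"
          } else {
            mr <- nearestTerm(models[[cat]], val, k = k,
                              acceptThreshold = acceptThreshold,
                              proposeThreshold = proposeThreshold)
            if (mr@decision == "auto") {
              entry$pass <- "nn_auto"
              entry$final <- mr@candidates$term[1L]
              entry$similarity <- mr@candidates$similarity[1L]
              entry$status <- "resolved"
            } else if (mr@decision == "proposed") {
              entry$status <- "proposed"
              cand <- cbind(mr@candidates, source = "nn",
                            stringsAsFactors = FALSE)
            } else {
              entry$status <- "unmatched"
              if (nrow(mr@candidates))
                cand <- cbind(mr@candidates, source = "nn",
                              stringsAsFactors = FALSE)
            }
          }
        }
        entries[[length(entries) + 1L]] <- entry
        candidates[[length(entries)]] <- cand
      }
    }
  }
  work <- if (length(entries)) do.call(rbind, entries)
          else emptyWorkEntries()
  length(candidates) <- nrow(work)
  attr(work, "candidates") <- candidates
  work
}

#' Second pass: substring rescue
#'
#' For every value the first pass could not resolve automatically, surfaces
#' that contain the value (or are contained in it) are added as proposed
#' candidates. Substring hits are never auto-applied; a value with no hit
#' stays unresolved for the third pass.
#'
#' @param work the working report from \code{\link{pass1Auto}}.
#' @param store a \linkS4class{VocabularyStore}.
#' @return the updated working report.
#' @export
pass2Substring <- function(work, store) {
  candidates <- attr(work, "candidates")
  todo <- which(work$status %in% c("proposed", "unmatched"))
  for (i in todo) {
    vocab <- store@vocabularies[[work$category[i]]]
    if (!length(vocab@mainTerms)) next
    hits <- substringMatch(vocab, work$original[i])
    if (!nrow(hits)) next
    sub <- data.frame(term = hits$term, surface = hits$surface,
                      similarity = hits$ratio, source = "substring",
                      stringsAsFactors = FALSE)
    candidates[[i]] <- rbind(candidates[[i]], sub)
    work$status[i] <- "proposed"
  }
  attr(work, "candidates") <- candidates
  work
}

pendingFrom <- function(work) {
  candidates <- attr(work, "candidates")
  idx <- which(!work$status %in% "resolved")
  if (!length(idx)) return(NULL)
  key <- confirmationKey(work$category[idx], work$original[idx])
  first <- idx[!duplicated(key)]
  pend <- data.frame(category = work$category[first],
                     original = work$original[first],
                     status = work$status[first],
                     stringsAsFactors = FALSE)
  pend$candidates <- lapply(first, function(i) {
    cc <- candidates[[i]]
    if (is.null(cc)) emptyCandidates() else cc
  })
  pend
}

stopPending <- function(pending) {
  msg <- sprintf(
    "confirmation required for %d value(s): %s",
    nrow(pending),
    paste(sprintf("%s='%s'", pending$category, pending$original),
          collapse = ", "))
  cond <- structure(
    class = c("metacurate_pending", "error", "condition"),
    list(message = msg, call = NULL, pending = pending))
  stop(cond)
}

#' Pending values of a needs-confirmation condition
#'
#' When \code{\link{standardize}} stops because unresolved values lack
#' confirmations, the thrown condition (class \code{metacurate_pending})
#' carries the pending table; this extracts it.
#'
#' @param cond the caught condition.
#' @return data.frame with columns \code{category}, \code{original},
#'   \code{status} and a \code{candidates} list-column.
#' @export
pendingValues <- function(cond) cond$pending

#' Third pass: confirmed proposals and new-term adoption
#'
#' Every value still unresolved must have a confirmation: an accepted
#' proposal (which must name one of the value's candidates -- recorded as
#' \code{nn_confirmed} or \code{substring} depending on which pass produced
#' it) or an accepted new term, which is added to the category's vocabulary
#' via \code{\link{addMainTerm}} (orthogonality enforced) with the models
#' refitted afterwards. Missing confirmations raise a
#' \code{metacurate_pending} condition enumerating the values; nothing is
#' mutated in that case.
#'
#' @param work the working report after \code{\link{pass2Substring}}.
#' @param confirmations a \linkS4class{ConfirmationSet}.
#' @param store a \linkS4class{VocabularyStore}.
#' @param models named list of fitted models.
#' @return list with \code{report} (a \linkS4class{CurationReport}),
#'   \code{store} and \code{models} (refitted for mutated categories).
#' @export
pass3NewTerms <- function(work, confirmations, store, models)
  resolvePass3(work, confirmations, store, models)

resolvePass3 <- function(work, confirmations, store, models) {
  candidates <- attr(work, "candidates")
  idx <- which(!work$status %in% "resolved")
  if (length(idx)) {
    keys <- confirmationKey(work$category[idx], work$original[idx])
    known <- keys %in% names(confirmations@proposals) |
             keys %in% names(confirmations@newTerms)
    if (any(!known)) {
      sub <- work[idx[!known], , drop = FALSE]
      attr(sub, "candidates") <- candidates[idx[!known]]
      sub$status <- work$status[idx[!known]]
      stopPending(pendingFrom(sub))
    }
    mutated <- character(0)
    for (i in idx) {
      key <- confirmationKey(work$category[i], work$original[i])
      if (key %in% names(confirmations@proposals)) {
        term <- confirmations@proposals[[key]]
        cc <- candidates[[i]]
        if (is.null(cc) || !term %in% cc$term)
          stop(sprintf(
            "accepted proposal '%s' is not a candidate for %s='%s'",
            term, work$category[i], work$original[i]), call. = FALSE)
        row <- cc[cc$term == term, , drop = FALSE][1L, ]
        work$pass[i] <- if (row$source == "substring") "substring"
                        else "nn_confirmed"
        work$final[i] <- term
        work$similarity[i] <- row$similarity
      } else {
        term <- confirmations@newTerms[[key]]
        store <- addMainTerm(store, work$category[i], term)
        mutated <- c(mutated, work$category[i])
        work$pass[i] <- "new_term"
        work$final[i] <- normalizeString(term)
        work$similarity[i] <- NA_real_
      }
      work$status[i] <- "resolved"
    }
    for (cat in unique(mutated))
      models[[cat]] <- fitTrigramModel(store@vocabularies[[cat]])
  }
  report <- new("CurationReport",
                entries = work[c("row", "category", "valueIndex",
                                 "original", "pass", "final",
                                 "similarity")])
  list(report = report, store = store, models = models)
}

#' CurationReport accessor
#' @param x a \linkS4class{CurationReport}.
#' @return the entries data.frame.
#' @export
reportEntries <- function(x) x@entries

#' Standardize a submission matrix
#'
#' The full three-pass pipeline. Pass 1 resolves values exactly, via
#' synonyms, or by nearest-neighbor matching above the accept threshold;
#' pass 2 adds substring candidates for what remains; pass 3 applies the
#' user's confirmations, adopting accepted new terms into the vocabularies
#' (with model refits). On success every non-empty controlled value of the
#' output matrix is a main term of the returned store -- the guarantee that
#' makes standardized matrices queryable by plain string equality. Multi
#' value cells are split on ";", curated per value, and rejoined in input
#' order. Vocabulary mutations are all-or-nothing: a failed run leaves the
#' store untouched.
#'
#' If unresolved values lack confirmations the call stops with a
#' \code{metacurate_pending} condition (see \code{\link{pendingValues}})
#' listing them with their candidates.
#'
#' @param x a \linkS4class{SubmissionMatrix}.
#' @param store a \linkS4class{VocabularyStore}.
#' @param models fitted models (default: freshly fitted from the store).
#' @param confirmations a \linkS4class{ConfirmationSet}.
#' @param acceptThreshold,proposeThreshold,k matcher settings.
#' @return list with \code{matrix} (standardized
#'   \linkS4class{SubmissionMatrix}), \code{report}
#'   (\linkS4class{CurationReport}), \code{store} and \code{models} (updated
#'   when new terms were adopted).
#' @examples
#' store <- vocabularyStore(vocabulary("species", "mus musculus",
#'                                     c(mouse = "mus musculus")))
#' m <- submissionMatrix(c("sampleLabel", "species"),
#'                       data.frame(sampleLabel = "s1", species = "Mouse"))
#' standardize(m, store)$matrix
#' @export
standardize <- function(x, store, models = fitModels(store),
                        confirmations = confirmationSet(),
                        acceptThreshold = 0.80, proposeThreshold = 0.20,
                        k = 5L) {
  validObject(x)
  work <- pass1Auto(x, store, models, acceptThreshold = acceptThreshold,
                    proposeThreshold = proposeThreshold, k = k)
  work <- pass2Substring(work, store)
  res <- resolvePass3(work, confirmations, store, models)
  entries <- res$report@entries
  out <- x@data
  for (ri in seq_len(nrow(out))) {
    for (cat in names(x@categories)) {
      sel <- entries$row == ri & entries$category == cat
      if (!any(sel)) next
      vals <- entries[sel, , drop = FALSE]
      if (nrow(vals) == 1L && vals$pass[1L] == "empty") {
        out[ri, cat] <- ""
      } else {
        vals <- vals[order(vals$valueIndex), , drop = FALSE]
        out[ri, cat] <- paste(vals$final, collapse = ";")
      }
    }
  }
  list(matrix = submissionMatrix(x@categories, out), report = res$report,
       store = res$store, models = res$models)
}
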
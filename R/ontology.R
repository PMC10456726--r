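#' Construct an OntologyGraph
#'
#' @param nodes data.frame with columns \code{id}, \code{name} and optionally
#'   \code{rank}.
#' @param synonyms named list: id -> character vector of synonyms.
#' @param headings named list: id -> character vector of tree numbers.
#' @param parents named list: id -> character vector of parent ids.
#' @return an \linkS4class{OntologyGraph}.
#' @export
ontologyGraph <- function(nodes, synonyms = list(), headings = list(),
                          parents = list()) {
  nodes$id <- as.character(nodes$id)
  nodes$name <- as.character(nodes$name)
  if (is.null(nodes$rank)) nodes$rank <- NA_character_
  new("OntologyGraph", nodes = nodes[c("id", "name", "rank")],
      synonyms = synonyms, headings = headings, parents = parents)
}

#' OntologyGraph accessors
#' @param x an \linkS4class{OntologyGraph}.
#' @return \code{graphNodes}: the node data.frame; \code{graphSynonyms}: the
#'   id -> synonyms list.
#' @export
graphNodes <- function(x) x@nodes

#' @rdname graphNodes
#' @export
graphSynonyms <- function(x) x@synonyms

stripFields <- function(line) {
  # taxdump rows are "field\t|\tfield\t|\t...\t|"
  f <- strsplit(line, "|", fixed = TRUE)[[1L]]
  gsub("^[\t ]+|[\t ]+$", "", f)
}

#' Read a taxdump-style ontology dump
#'
#' The ranked-taxonomy dialect: a pipe-delimited node table (node id, parent
#' id, rank) and a name table (node id, name, name class). The row whose name
#' class is \code{"scientific name"} becomes the node's name; rows of every
#' other class (common name, synonym, ...) become synonyms. A node whose
#' parent is itself is the root (the self-edge is dropped).
#'
#' @param nodesPath path to the node table.
#' @param namesPath path to the name table.
#' @return an \linkS4class{OntologyGraph}.
#' @export
readTaxdumpDialect <- function(nodesPath, namesPath) {
  nodeLines <- readLines(nodesPath, warn = FALSE)
  nodeLines <- nodeLines[nzchar(nodeLines)]
  ids <- character(length(nodeLines))
  parentOf <- character(length(nodeLines))
  ranks <- character(length(nodeLines))
  for (i in seq_along(nodeLines)) {
    f <- stripFields(nodeLines[[i]])
    if (length(f) < 3L)
      stop(sprintf("%s:%d: expected id|parent|rank", nodesPath, i),
           call. = FALSE)
    ids[i] <- f[[1L]]; parentOf[i] <- f[[2L]]; ranks[i] <- f[[3L]]
  }
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate node id '%s'", nodesPath,
                 ids[duplicated(ids)][1L]), call. = FALSE)
  dangling <- setdiff(parentOf, ids)
  if (length(dangling))
    stop(sprintf("%s: dangling parent id '%s'", nodesPath, dangling[1L]),
         call. = FALSE)
  nameLines <- readLines(namesPath, warn = FALSE)
  nameLines <- nameLines[nzchar(nameLines)]
  sciName <- stats::setNames(rep(NA_character_, length(ids)), ids)
  synonyms <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(nameLines)) {
    f <- stripFields(nameLines[[i]])
    if (length(f) < 3L)
      stop(sprintf("%s:%d: expected id|name|name class", namesPath, i),
           call. = FALSE)
    id <- f[[1L]]
    if (!id %in% ids)
      stop(sprintf("%s:%d: name for unknown node '%s'", namesPath, i, id),
           call. = FALSE)
    if (f[[3L]] == "scientific name") {
      if (!is.na(sciName[[id]]))
        stop(sprintf("%s:%d: duplicate scientific name for node '%s'",
                     namesPath, i, id), call. = FALSE)
      sciName[[id]] <- f[[2L]]
    } else {
      synonyms[[id]] <- c(synonyms[[id]], f[[2L]])
    }
  }
  missing <- ids[is.na(sciName)]
  if (length(missing))
    stop(sprintf("%s: node '%s' has no scientific name", namesPath,
                 missing[1L]), call. = FALSE)
  parents <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    if (parentOf[i] != ids[i]) parents[[ids[i]]] <- parentOf[i]
    else parents[[ids[i]]] <- character(0)
  }
  synonyms <- synonyms[!vapply(synonyms, is.null, logical(1))]
  ontologyGraph(
    data.frame(id = ids, name = unname(sciName[ids]), rank = ranks,
               stringsAsFactors = FALSE),
    synonyms = synonyms, parents = parents)
}

validHeading <- function(h)
  grepl("^[A-Za-z][0-9A-Za-z]*(\\.[0-9A-Za-z]+)*$", h)

# Parent tree number: strip the last dot segment; a dotless number like A01
# falls back to its letter prefix (A01 sits under heading class A). Segments
# are never split mid-way, so A01 is not a parent of A011.
headingParentOf <- function(h) {
  if (grepl(".", h, fixed = TRUE)) return(sub("\\.[^.]+$", "", h))
  sub("[0-9]+$", "", h)
}

# is heading h at or below prefix r (segment-wise; a bare letter covers its
# whole heading class)
headingUnder <- function(h, r) {
  h == r || startsWith(h, paste0(r, ".")) ||
    (grepl("^[A-Za-z]$", r) && startsWith(h, r))
}

#' Read a tree-number-style ontology dump
#'
#' The heading-prefixed descriptor dialect: a headered TSV of
#' (term, headings, synonyms) where headings and synonyms are ";"-separated.
#' Parentage is inferred from dot-separated tree-number containment: the
#' parent of the node holding heading A01.111 is the node holding A01 --
#' segment-wise, so A01 is never the parent of A011. A node with k headings
#' has up to k parents. Ranks do not exist in this dialect.
#'
#' @param path path to the TSV (columns term, headings, synonyms; header row
#'   required).
#' @return an \linkS4class{OntologyGraph}; node ids are the term strings.
#' @export
readTreeNumberDialect <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(ontologyGraph(data.frame(id = character(), name = character(),
                                    rank = character())))
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[[1L]] != "term")
    stop(sprintf("%s:1: header must start 'term\theadings[\tsynonyms]'",
                 path), call. = FALSE)
  splitSemi <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  }
  terms <- character(0); headings <- list(); synonyms <- list()
  for (i in seq_along(lines)[-1L]) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    length(f) <- 3L
    term <- f[[1L]]
    if (is.na(term) || !nzchar(term))
      stop(sprintf("%s:%d: empty term", path, i), call. = FALSE)
    hs <- splitSemi(f[[2L]])
    bad <- hs[!validHeading(hs)]
    if (length(bad))
      stop(sprintf("%s:%d: malformed tree number '%s'", path, i, bad[[1L]]),
           call. = FALSE)
    terms <- c(terms, term)
    headings[[term]] <- hs
    sy <- splitSemi(f[[3L]])
    if (length(sy)) synonyms[[term]] <- sy
  }
  if (anyDuplicated(terms))
    stop(sprintf("%s: duplicate term '%s'", path,
                 terms[duplicated(terms)][1L]), call. = FALSE)
  # owner of each tree number
  owner <- stats::setNames(rep(names(headings), lengths(headings)),
                           unlist(headings, use.names = FALSE))
  parents <- stats::setNames(vector("list", length(terms)), terms)
  for (term in terms) {
    ps <- character(0)
    for (h in headings[[term]]) {
      up <- headingParentOf(h)
      if (up != h && nzchar(up) && up %in% names(owner))
        ps <- c(ps, owner[[up]])
    }
    parents[[term]] <- setdiff(unique(ps), term)
  }
  ontologyGraph(
    data.frame(id = terms, name = terms, rank = NA_character_,
               stringsAsFactors = FALSE),
    synonyms = synonyms, headings = headings, parents = parents)
}

childrenMap <- function(graph) {
  kids <- stats::setNames(vector("list", nrow(graph@nodes)),
                          graph@nodes$id)
  for (id in names(graph@parents))
    for (p in graph@parents[[id]]) kids[[p]] <- c(kids[[p]], id)
  kids
}

descendantsOf <- function(graph, seeds, kids = childrenMap(graph)) {
  seen <- character(0)
  queue <- unique(seeds)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, kids[[v]])
  }
  seen
}

resolveRoots <- function(graph, roots) {
  ids <- graph@nodes$id
  out <- character(0)
  for (r in roots) {
    if (r %in% ids) { out <- c(out, r); next }
    # heading prefix: nodes with a tree number at or below r
    hit <- vapply(ids, function(id) {
      hs <- graph@headings[[id]]
      length(hs) > 0 && any(vapply(hs, headingUnder, logical(1), r = r))
    }, logical(1))
    if (!any(hit))
      stop(sprintf("unknown root '%s'", r), call. = FALSE)
    out <- c(out, ids[hit])
  }
  unique(out)
}

#' Extract the terms of one or more subtrees
#'
#' Returns every node that is a listed root or a descendant of one; a node
#' reachable from two roots appears once. Roots may be node ids or (for the
#' tree-number dialect) heading prefixes, where the prefix relation is by
#' dot-separated segment (\code{A01} covers \code{A01.111}, not
#' \code{A011}).
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param roots character vector of node ids or heading prefixes.
#' @return data.frame with columns \code{id} and \code{name}.
#' @export
subtreeTerms <- function(graph, roots) {
  seeds <- resolveRoots(graph, roots)
  ids <- descendantsOf(graph, seeds)
  sub <- graph@nodes[graph@nodes$id %in% ids, c("id", "name")]
  rownames(sub) <- NULL
  sub
}

#' Exclusion rules for vocabulary extraction
#'
#' The closed rule set used to subset an ontology into a vocabulary. Rules
#' are applied conjunctively (a node survives only if no rule drops it), so
#' rule order never matters. Substring matching is case-insensitive on
#' normalized names.
#'
#' \describe{
#'   \item{\code{dropRank(rank)}}{drop every node of that rank (e.g. all
#'     rank-"strain" taxa).}
#'   \item{\code{dropDescendantsOfNameContaining(substring)}}{drop every node
#'     whose name contains the substring, together with its whole subtree
#'     (e.g. everything under "environmental samples").}
#'   \item{\code{dropRankNameContaining(rank, substring)}}{drop nodes of the
#'     given rank whose name contains the substring (e.g. rank "no rank"
#'     containing "/").}
#'   \item{\code{dropRankNameMatchingDigits(rank)}}{drop nodes of the given
#'     rank whose name contains a decimal digit.}
#'   \item{\code{subtractReferenceRule(terms)}}{drop nodes whose normalized
#'     name appears in a reference term set (used to keep vocabularies
#'     orthogonal at build time).}
#' }
#'
#' @param rank rank string as stored in the dump.
#' @param substring substring sought in normalized node names.
#' @param terms character vector of reference terms.
#' @return an exclusion rule for \code{\link{extractionSpec}}.
#' @export
dropRank <- function(rank) list(type = "drop_rank", rank = rank)

#' @rdname dropRank
#' @export
dropDescendantsOfNameContaining <- function(substring)
  list(type = "drop_descendants_of_name_containing", substring = substring)

#' @rdname dropRank
#' @export
dropRankNameContaining <- function(rank, substring)
  list(type = "drop_rank_name_containing", rank = rank,
       substring = substring)

#' @rdname dropRank
#' @export
dropRankNameMatchingDigits <- function(rank)
  list(type = "drop_rank_name_matching_digits", rank = rank)

#' @rdname dropRank
#' @export
subtractReferenceRule <- function(terms)
  list(type = "subtract_reference", terms = normalizeString(terms))

#' Construct an ExtractionSpec
#'
#' @param includeRoots node ids or heading prefixes anchoring the subtrees.
#' @param exclusions list of rules built with \code{\link{dropRank}} and
#'   friends.
#' @return an \linkS4class{ExtractionSpec}.
#' @export
extractionSpec <- function(includeRoots, exclusions = list())
  new("ExtractionSpec", includeRoots = as.character(includeRoots),
      exclusions = exclusions)

ruleDropSet <- function(rule, graph, kids) {
  nodes <- graph@nodes
  normNames <- normalizeString(nodes$name)
  switch(rule$type,
    drop_rank = nodes$id[!is.na(nodes$rank) & nodes$rank == rule$rank],
    drop_descendants_of_name_containing = {
      flagged <- nodes$id[grepl(normalizeString(rule$substring), normNames,
                                fixed = TRUE)]
      if (length(flagged)) descendantsOf(graph, flagged, kids)
      else character(0)
    },
    drop_rank_name_containing =
      nodes$id[!is.na(nodes$rank) & nodes$rank == rule$rank &
               grepl(normalizeString(rule$substring), normNames,
                     fixed = TRUE)],
    drop_rank_name_matching_digits =
      nodes$id[!is.na(nodes$rank) & nodes$rank == rule$rank &
               grepl("[0-9]", nodes$name)],
    subtract_reference = nodes$id[normNames %in% rule$terms],
    stop("unknown exclusion rule type: ", rule$type, call. = FALSE))
}

#' Apply exclusion rules to candidate nodes
#'
#' Every rule is evaluated against the full graph and the union of their
#' drop sets is removed from the candidates; permuting the rule list cannot
#' change the result.
#'
#' @param candidates character vector of candidate node ids.
#' @param graph the \linkS4class{OntologyGraph} the candidates come from.
#' @param exclusions list of rules (see \code{\link{dropRank}}).
#' @return the surviving candidate ids.
#' @export
applyExclusions <- function(candidates, graph, exclusions) {
  if (!length(exclusions)) return(candidates)
  kids <- childrenMap(graph)
  dropped <- unique(unlist(lapply(exclusions, ruleDropSet, graph = graph,
                                  kids = kids)))
  setdiff(candidates, dropped)
}

#' Set-difference against a reference vocabulary
#'
#' Removes from \code{terms} every string present in \code{reference}; both
#' sides are normalized. Used at build time to keep a new vocabulary
#' orthogonal to an existing one (e.g. strain terms already present in the
#' species vocabulary).
#'
#' @param terms character vector.
#' @param reference character vector.
#' @return \code{terms} minus \code{reference}, normalized and deduplicated.
#' @export
subtractReference <- function(terms, reference)
  setdiff(unique(normalizeString(terms)), normalizeString(reference))

#' Build a Vocabulary from an ontology graph
#'
#' Extracts the subtrees under the spec's roots, applies the exclusion rules
#' conjunctively, and turns the surviving node names (normalized,
#' deduplicated) into main terms. Node synonyms become synonym entries unless
#' they collide with a main term of the same vocabulary, in which case the
#' synonym is dropped (main terms are the identity anchors) and reported via
#' a message.
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param spec an \linkS4class{ExtractionSpec}.
#' @param category target \linkS4class{CategorySpec} or standard category
#'   name.
#' @return a \linkS4class{Vocabulary}.
#' @export
buildVocabulary <- function(graph, spec, category) {
  validObject(spec)
  sub <- subtreeTerms(graph, spec@includeRoots)
  keep <- applyExclusions(sub$id, graph, spec@exclusions)
  nodes <- graph@nodes[match(keep, graph@nodes$id), ]
  mains <- unique(normalizeString(nodes$name))
  mains <- mains[nzchar(mains)]
  synKeys <- character(0); synVals <- character(0)
  for (i in seq_len(nrow(nodes))) {
    main <- normalizeString(nodes$name[i])
    for (s in graph@synonyms[[nodes$id[i]]]) {
      s <- normalizeString(s)
      if (!nzchar(s)) next
      if (s %in% mains) {
        message(sprintf(
          "dropping synonym '%s' (collides with a main term of '%s')",
          s, if (is.character(category)) category else category@name))
        next
      }
      synKeys <- c(synKeys, s); synVals <- c(synVals, main)
    }
  }
  vocabulary(category, mains, stats::setNames(synVals, synKeys))
}

#' Read an ExtractionSpec from JSON
#'
#' The machine-readable form used by the command-line \code{build-vocab}
#' subcommand: \code{{"include_roots": [...], "exclusions": [{"type": ...,
#' "rank": ..., "substring": ..., "terms": [...]}]}}.
#'
#' @param path JSON file path.
#' @return an \linkS4class{ExtractionSpec}.
#' @export
readExtractionSpec <- function(path) {
  x <- jsonlite::read_json(path)
  rules <- lapply(x$exclusions, function(r) {
    switch(r$type,
      drop_rank = dropRank(r$rank),
      drop_descendants_of_name_containing =
        dropDescendantsOfNameContaining(r$substring),
      drop_rank_name_containing =
        dropRankNameContaining(r$rank, r$substring),
      drop_rank_name_matching_digits =
        dropRankNameMatchingDigits(r$rank),
      subtract_reference =
        subtractReferenceRule(unlist(r$terms, use.names = FALSE)),
      stop("unknown exclusion rule type: ", r$type, call. = FALSE))
  })
  extractionSpec(unlist(x$include_roots, use.names = FALSE), rules)
}
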
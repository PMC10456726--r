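#' Create a MetadataRepository
#'
#' The programmatic access point over a vocabulary store: it serves
#' vocabulary queries and match/standardize requests, persists standardized
#' studies (re-validating the guarantee invariant on ingest) and answers
#' string-equality sample queries. All mutators return the updated
#' repository; persistence is file-backed via \code{\link{saveRepository}}.
#'
#' @param store a \linkS4class{VocabularyStore}.
#' @param models fitted models (default: fitted from the store).
#' @return a \linkS4class{MetadataRepository}.
#' @export
newRepository <- function(store, models = fitModels(store)) {
  new("MetadataRepository", store = store, models = models,
      studies = list())
}

#' Repository accessors
#' @param x a \linkS4class{MetadataRepository}.
#' @return \code{repoStore}: the \linkS4class{VocabularyStore};
#'   \code{repoStudies}: named list of \linkS4class{StoredStudy};
#'   \code{repoModels}: named list of fitted models.
#' @export
repoStore <- function(x) x@store

#' @rdname repoStore
#' @export
repoStudies <- function(x) x@studies

#' @rdname repoStore
#' @export
repoModels <- function(x) x@models

# guarantee re-validation: every non-empty delimited value of a controlled
# column must be a main term of the repository's store
guaranteeViolations <- function(store, x) {
  bad <- list()
  df <- x@data
  for (cat in names(x@categories)) {
    if (classifyCell(store, cat) != "controlled") next
    terms <- store@vocabularies[[cat]]@mainTerms
    for (ri in seq_len(nrow(df))) {
      for (val in splitCell(df[ri, cat])) {
        if (!val %in% terms)
          bad[[length(bad) + 1L]] <- data.frame(
            row = ri, category = cat, value = val,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(bad))
    return(data.frame(row = integer(), category = character(),
                      value = character(), stringsAsFactors = FALSE))
  do.call(rbind, bad)
}

#' Store a standardized study
#'
#' The matrix is re-validated on ingest: every non-empty controlled value
#' must be a main term of the repository's current store, otherwise the
#' submission is rejected.
#'
#' @param repo a \linkS4class{MetadataRepository}.
#' @param x a standardized \linkS4class{SubmissionMatrix}.
#' @param author author string.
#' @param report optional \linkS4class{CurationReport} of the
#'   standardization run.
#' @param id study id (default: next sequential id).
#' @return the updated repository; the new id is in
#'   \code{attr(, "studyId")}.
#' @export
addStudy <- function(repo, x, author = "", report = NULL, id = NULL) {
  validObject(x)
  viol <- guaranteeViolations(repo@store, x)
  if (nrow(viol))
    stop(sprintf(
      "matrix violates the standardization guarantee (%d value(s), e.g. %s='%s')",
      nrow(viol), viol$category[1L], viol$value[1L]), call. = FALSE)
  if (is.null(id)) id <- sprintf("study-%04d", length(repo@studies) + 1L)
  if (id %in% names(repo@studies))
    stop(sprintf("study id '%s' already exists", id), call. = FALSE)
  if (is.null(report))
    report <- new("CurationReport", entries = data.frame(
      row = integer(), category = character(), valueIndex = integer(),
      original = character(), pass = character(), final = character(),
      similarity = numeric(), stringsAsFactors = FALSE))
  study <- new("StoredStudy", id = id, author = author,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               matrix = x, report = report)
  repo@studies[[id]] <- study
  attr(repo, "studyId") <- id
  repo
}

#' Query stored samples by string equality
#'
#' A sample matches when, for every filter, the delimited value set of its
#' cell in that category contains the filter value (conjunction across
#' filters; values are normalized before comparison). An empty filter list
#' matches every sample.
#'
#' @param repo a \linkS4class{MetadataRepository}.
#' @param filters named character vector or named list:
#'   category -> value. Repeated categories are allowed via a list of
#'   \code{c(category, value)} pairs.
#' @return data.frame with columns \code{study} and \code{row}.
#' @export
querySamples <- function(repo, filters = character()) {
  if (is.list(filters) && length(filters) &&
      is.null(names(filters))) {
    pairs <- lapply(filters, function(p) c(p[[1L]], p[[2L]]))
  } else {
    pairs <- Map(c, names(filters), unname(unlist(filters)))
  }
  for (p in pairs) {
    if (!p[[1L]] %in% names(repo@store@categories))
      stop(sprintf("unknown category '%s'", p[[1L]]), call. = FALSE)
  }
  out <- list()
  for (study in repo@studies) {
    df <- study@matrix@data
    cats <- names(study@matrix@categories)
    for (ri in seq_len(nrow(df))) {
      ok <- TRUE
      for (p in pairs) {
        cat <- p[[1L]]; val <- normalizeString(p[[2L]])
        if (!cat %in% cats) { ok <- FALSE; break }
        vals <- normalizeString(splitCell(df[ri, cat]))
        if (!val %in% vals) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1L]] <-
        data.frame(study = study@id, row = ri, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(study = character(), row = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Save / load a repository directory
#'
#' File-backed persistence: the vocabulary store (TSVs + manifest), the
#' fitted models, and one CSV + report JSON per stored study.
#'
#' @param repo a \linkS4class{MetadataRepository}.
#' @param dir directory path.
#' @return \code{saveRepository}: \code{dir}, invisibly;
#'   \code{loadRepository}: a \linkS4class{MetadataRepository}.
#' @export
saveRepository <- function(repo, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveStore(repo@store, file.path(dir, "vocabularies"))
  modelDir <- file.path(dir, "models")
  if (!dir.exists(modelDir)) dir.create(modelDir)
  for (nm in names(repo@models))
    saveModel(repo@models[[nm]], file.path(modelDir, paste0(nm, ".json")))
  studyDir <- file.path(dir, "studies")
  if (!dir.exists(studyDir)) dir.create(studyDir)
  index <- lapply(repo@studies, function(st)
    list(id = st@id, author = st@author, timestamp = st@timestamp))
  jsonlite::write_json(unname(index), file.path(studyDir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (st in repo@studies) {
    writeSubmission(st@matrix, file.path(studyDir, paste0(st@id, ".csv")))
    jsonlite::write_json(st@report@entries,
                         file.path(studyDir, paste0(st@id, "-report.json")),
                         dataframe = "rows", na = "null")
  }
  invisible(dir)
}

#' @rdname saveRepository
#' @export
loadRepository <- function(dir) {
  store <- loadStore(file.path(dir, "vocabularies"))
  modelDir <- file.path(dir, "models")
  models <- list()
  for (f in list.files(modelDir, pattern = "\\.json$", full.names = TRUE))
    models[[sub("\\.json$", "", basename(f))]] <- loadModel(f)
  repo <- newRepository(store, models)
  studyDir <- file.path(dir, "studies")
  indexPath <- file.path(studyDir, "index.json")
  if (file.exists(indexPath)) {
    for (entry in jsonlite::read_json(indexPath)) {
      m <- readSubmission(file.path(studyDir, paste0(entry$id, ".csv")),
                          categories = store@categories)
      reportPath <- file.path(studyDir, paste0(entry$id, "-report.json"))
      entries <- jsonlite::read_json(reportPath, simplifyVector = TRUE)
      if (!length(entries))
        entries <- data.frame(row = integer(), category = character(),
                              valueIndex = integer(),
                              original = character(), pass = character(),
                              final = character(), similarity = numeric())
      entries$similarity <- as.numeric(entries$similarity)
      report <- new("CurationReport", entries = entries)
      repo@studies[[entry$id]] <- new(
        "StoredStudy", id = entry$id, author = entry$author,
        timestamp = entry$timestamp, matrix = m, report = report)
    }
  }
  repo
}

jsonResponse <- function(status, body, repo = NULL)
  list(status = status, body = body, repo = repo)

matrixFromPayload <- function(body, store) {
  cats <- unlist(body$categories, use.names = FALSE)
  unknown <- setdiff(cats, names(store@categories))
  if (length(unknown))
    stop(sprintf("unknown categories: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  rows <- lapply(body$rows, function(r)
    unlist(lapply(r, function(v) if (is.null(v)) "" else as.character(v)),
           use.names = FALSE))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(df) <- cats
  submissionMatrix(store@categories[cats], df)
}

matrixPayload <- function(x)
  list(categories = names(x@categories),
       rows = lapply(seq_len(nrow(x@data)), function(i)
         as.list(unname(unlist(x@data[i, , drop = TRUE])))))

confirmationsFromPayload <- function(body) {
  conf <- confirmationSet()
  for (p in body$proposals)
    conf <- confirmProposal(conf, p$category, p$original, p$term)
  for (p in body$new_terms)
    conf <- confirmNewTerm(conf, p$category, p$original,
                           if (is.null(p$term)) p$original else p$term)
  conf
}

#' Handle one API request against a repository
#'
#' An in-process dispatcher over the repository, one call per request, with
#' JSON-able request and response bodies -- the endpoint surface a web layer
#' would mount. Supported routes:
#' \itemize{
#'   \item \code{GET /categories} -- all registered categories.
#'   \item \code{GET /vocabularies/<category>/terms} -- main terms, with
#'     optional \code{prefix} filter and \code{offset}/\code{limit}
#'     pagination.
#'   \item \code{POST /match} -- body \code{category} + \code{strings};
#'     ranked match results per string.
#'   \item \code{POST /standardize} -- body \code{matrix} (+ optional
#'     \code{confirmations}); the standardized matrix and report, or a 409
#'     needs-confirmation payload listing pending values with candidates.
#'     Adopted new terms update the repository's store and models.
#'   \item \code{POST /studies} -- persist a standardized matrix (guarantee
#'     re-validated; violations are a 422).
#'   \item \code{GET /studies} -- the study index.
#'   \item \code{GET /samples} -- string-equality sample query; the query
#'     list is category = value pairs.
#' }
#' A mismatch between the store's vocabulary versions and the fitted models
#' is refused with a 503 retrain-required signal.
#'
#' @param repo a \linkS4class{MetadataRepository}.
#' @param method "GET" or "POST".
#' @param path the route.
#' @param query named list of query parameters.
#' @param body request body as an R list (parsed JSON).
#' @return list with \code{status} (integer HTTP-style code), \code{body}
#'   (JSON-able list) and \code{repo} (the possibly updated repository).
#' @export
handleRequest <- function(repo, method, path, query = list(),
                          body = list()) {
  route <- paste(method, path)
  store <- repo@store
  tryCatch({
    if (route == "GET /categories") {
      out <- lapply(store@categories, function(cs)
        list(name = cs@name, grouping = cs@grouping,
             value_class = cs@valueClass))
      return(jsonResponse(200L, unname(out), repo))
    }
    m <- regmatches(path,
                    regexec("^/vocabularies/([^/]+)/terms$", path))[[1L]]
    if (method == "GET" && length(m) == 2L) {
      category <- m[[2L]]
      assertControlled(store, category)
      terms <- store@vocabularies[[category]]@mainTerms
      if (!is.null(query$prefix))
        terms <- terms[startsWith(terms, normalizeString(query$prefix))]
      total <- length(terms)
      offset <- if (is.null(query$offset)) 0L
                else as.integer(query$offset)
      limit <- if (is.null(query$limit)) total else as.integer(query$limit)
      terms <- terms[seq_along(terms) > offset &
                     seq_along(terms) <= offset + limit]
      return(jsonResponse(200L, list(
        category = category, total = total, offset = offset,
        terms = as.list(terms),
        version = store@vocabularies[[category]]@version), repo))
    }
    if (route == "POST /match") {
      category <- body$category
      assertControlled(store, category)
      model <- repo@models[[category]]
      if (is.null(model))
        return(jsonResponse(422L, list(
          error = sprintf("category '%s' has an empty vocabulary",
                          category)), repo))
      if (!modelCurrent(model, store))
        return(jsonResponse(503L, list(error = "retrain required"), repo))
      strings <- unlist(body$strings, use.names = FALSE)
      results <- lapply(strings, function(s) {
        mr <- nearestTerm(model, s)
        list(query = s, decision = mr@decision,
             candidates = lapply(seq_len(nrow(mr@candidates)), function(i)
               list(term = mr@candidates$term[i],
                    surface = mr@candidates$surface[i],
                    similarity = mr@candidates$similarity[i])))
      })
      return(jsonResponse(200L, results, repo))
    }
    if (route == "POST /standardize") {
      for (nm in names(repo@models))
        if (!modelCurrent(repo@models[[nm]], store))
          return(jsonResponse(503L, list(error = "retrain required"), repo))
      x <- matrixFromPayload(body$matrix, store)
      conf <- confirmationsFromPayload(body$confirmations)
      res <- tryCatch(
        standardize(x, store, repo@models, conf),
        metacurate_pending = function(cond) cond)
      if (inherits(res, "metacurate_pending")) {
        pend <- pendingValues(res)
        payload <- lapply(seq_len(nrow(pend)), function(i) list(
          category = pend$category[i], original = pend$original[i],
          candidates = lapply(seq_len(nrow(pend$candidates[[i]])),
            function(j) list(
              term = pend$candidates[[i]]$term[j],
              similarity = pend$candidates[[i]]$similarity[j],
              source = pend$candidates[[i]]$source[j]))))
        return(jsonResponse(409L,
          list(needs_confirmation = payload), repo))
      }
      repo@store <- res$store
      repo@models <- res$models
      return(jsonResponse(200L, list(
        matrix = matrixPayload(res$matrix),
        report = reportToPayload(res$report)), repo))
    }
    if (route == "POST /studies") {
      x <- matrixFromPayload(body$matrix, store)
      repo2 <- tryCatch(
        addStudy(repo, x, author = if (is.null(body$author)) ""
                                   else body$author),
        error = function(e) e)
      if (inherits(repo2, "error"))
        return(jsonResponse(422L, list(error = conditionMessage(repo2)),
                            repo))
      return(jsonResponse(201L, list(id = attr(repo2, "studyId")), repo2))
    }
    if (route == "GET /studies") {
      out <- lapply(repo@studies, function(st)
        list(id = st@id, author = st@author, timestamp = st@timestamp,
             samples = nrow(st@matrix@data)))
      return(jsonResponse(200L, unname(out), repo))
    }
    if (route == "GET /samples") {
      hits <- querySamples(repo, query)
      out <- lapply(seq_len(nrow(hits)), function(i)
        list(study = hits$study[i], row = hits$row[i]))
      return(jsonResponse(200L, out, repo))
    }
    jsonResponse(404L, list(error = sprintf("no route %s", route)), repo)
  }, error = function(e)
    jsonResponse(400L, list(error = conditionMessage(e)), repo))
}

reportToPayload <- function(report) {
  e <- report@entries
  lapply(seq_len(nrow(e)), function(i) list(
    row = e$row[i], category = e$category[i],
    value_index = e$valueIndex[i], original = e$original[i],
    pass = e$pass[i], final = e$final[i],
    similarity = if (is.na(e$similarity[i])) NULL else e$similarity[i]))
}
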
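#' Save / load a Vocabulary as TSV
#'
#' One file per category. Columns are exactly \code{term}, \code{role}
#' (\code{main} or \code{synonym}) and \code{maps_to} (empty for main rows,
#' the main term for synonym rows); tab-delimited UTF-8 with a header row.
#' \code{loadVocab(saveVocab(v))} reproduces the vocabulary field for field.
#'
#' @param v a \linkS4class{Vocabulary}.
#' @param path file path.
#' @param category for \code{loadVocab}: the \linkS4class{CategorySpec} (or
#'   standard category name) the file belongs to.
#' @param version version to stamp on the loaded vocabulary (default 1).
#' @return \code{saveVocab}: the path, invisibly. \code{loadVocab}: a
#'   \linkS4class{Vocabulary}.
#' @export
saveVocab <- function(v, path) {
  df <- data.frame(
    term = c(v@mainTerms, names(v@synonymMap)),
    role = c(rep("main", length(v@mainTerms)),
             rep("synonym", length(v@synonymMap))),
    maps_to = c(rep("", length(v@mainTerms)), unname(v@synonymMap)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname saveVocab
#' @export
loadVocab <- function(path, category, version = 1L) {
  if (is.character(category)) category <- standardCategory(category)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty vocabulary file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("term", "role", "maps_to")))
    stop(sprintf("%s:1: header must be 'term\trole\tmaps_to'", path),
         call. = FALSE)
  main <- character(0)
  synKeys <- character(0)
  synVals <- character(0)
  seen <- character(0)
  for (i in seq_along(lines)[-1L]) {
    if (!nzchar(lines[[i]])) next
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    length(f) <- 3L
    f[is.na(f)] <- ""
    term <- f[[1L]]; role <- f[[2L]]; mapsTo <- f[[3L]]
    if (!nzchar(term))
      stop(sprintf("%s:%d: empty term", path, i), call. = FALSE)
    if (term %in% seen)
      stop(sprintf("%s:%d: duplicate term row '%s'", path, i, term),
           call. = FALSE)
    seen <- c(seen, term)
    if (role == "main") {
      if (nzchar(mapsTo))
        stop(sprintf("%s:%d: main row must have empty maps_to", path, i),
             call. = FALSE)
      main <- c(main, term)
    } else if (role == "synonym") {
      if (!nzchar(mapsTo))
        stop(sprintf("%s:%d: synonym row needs maps_to", path, i),
             call. = FALSE)
      synKeys <- c(synKeys, term)
      synVals <- c(synVals, mapsTo)
    } else {
      stop(sprintf("%s:%d: malformed role '%s'", path, i, role),
           call. = FALSE)
    }
  }
  dangling <- setdiff(synVals, main)
  if (length(dangling)) {
    at <- which(synVals %in% dangling)[1L]
    line <- which(lines == paste(synKeys[at], "synonym", synVals[at],
                                 sep = "\t"))[1L]
    stop(sprintf("%s:%d: dangling maps_to '%s'", path,
                 if (is.na(line)) at + 1L else line, synVals[at]),
         call. = FALSE)
  }
  vocabulary(category, main, stats::setNames(synVals, synKeys),
             version = version)
}

#' Save / load a whole VocabularyStore as a directory
#'
#' Writes one TSV per controlled category plus \code{manifest.json} listing
#' every registered category with its grouping, value class and (for
#' controlled categories) current vocabulary version.
#'
#' @param store a \linkS4class{VocabularyStore}.
#' @param dir directory path (created if absent).
#' @return \code{saveStore}: \code{dir}, invisibly. \code{loadStore}: a
#'   \linkS4class{VocabularyStore}.
#' @export
saveStore <- function(store, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- lapply(store@categories, function(cs) {
    entry <- list(name = cs@name, grouping = cs@grouping,
                  value_class = cs@valueClass)
    if (cs@valueClass == "controlled")
      entry$version <- store@vocabularies[[cs@name]]@version
    entry
  })
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (nm in names(store@vocabularies))
    saveVocab(store@vocabularies[[nm]],
              file.path(dir, paste0(nm, ".tsv")))
  invisible(dir)
}

#' @rdname saveStore
#' @export
loadStore <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath))
    stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(manifestPath)
  categories <- list()
  vocabularies <- list()
  for (entry in manifest) {
    cs <- categorySpec(entry$name, entry$grouping, entry$value_class)
    categories[[cs@name]] <- cs
    if (cs@valueClass == "controlled") {
      path <- file.path(dir, paste0(cs@name, ".tsv"))
      if (!file.exists(path))
        stop("missing vocabulary file for category ", cs@name, call. = FALSE)
      vocabularies[[cs@name]] <- loadVocab(
        path, cs, version = if (is.null(entry$version)) 1L
                            else as.integer(entry$version))
    }
  }
  new("VocabularyStore", categories = categories,
      vocabularies = vocabularies)
}
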
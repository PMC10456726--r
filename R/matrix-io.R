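#' Construct a SubmissionMatrix
#'
#' @param categories list of \linkS4class{CategorySpec} (or character vector
#'   of standard category names) in column order. Must include sampleLabel.
#' @param data data.frame (or anything coercible) of character cells, one
#'   column per category; zero rows gives an empty template.
#' @return a \linkS4class{SubmissionMatrix}.
#' @export
submissionMatrix <- function(categories, data = NULL) {
  if (is.character(categories))
    categories <- lapply(categories, standardCategory)
  names(categories) <- vapply(categories, function(x) x@name, character(1))
  if (is.null(data)) {
    data <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(categories)),
                      names(categories)),
      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    data <- as.data.frame(data, check.names = FALSE,
                          stringsAsFactors = FALSE)
    data[] <- lapply(data, as.character)
    colnames(data) <- names(categories)
  }
  new("SubmissionMatrix", categories = categories, data = data)
}

#' SubmissionMatrix accessors
#' @param x a \linkS4class{SubmissionMatrix}.
#' @return \code{matrixData}: the character data.frame;
#'   \code{matrixCategories}: the ordered named list of
#'   \linkS4class{CategorySpec}; \code{nSamples}: the row count.
#' @export
matrixData <- function(x) x@data

#' @rdname matrixData
#' @export
matrixCategories <- function(x) x@categories

#' @rdname matrixData
#' @export
nSamples <- function(x) nrow(x@data)

#' Build an empty submission-matrix template from a schema selection
#'
#' The first component of the user flow: pick at least one core sample type
#' (species, organ, cellLine, material) plus any additional categories, and
#' receive a headered, zero-row matrix to fill in. sampleLabel is always
#' present and first; after it, columns are ordered by grouping
#' (CoreSampleType, SampleDescription, StudyFactors, TimeSeries, Other)
#' preserving the user's order within each group. A unit category may only
#' appear together with its magnitude partner (ageUnit with age, ...).
#'
#' @param selection character vector of standard category names (sampleLabel
#'   is implied and need not be listed).
#' @return a zero-row \linkS4class{SubmissionMatrix}.
#' @examples
#' buildSchema(c("species", "organ", "sex", "age", "ageUnit"))
#' @export
buildSchema <- function(selection) {
  if (anyDuplicated(selection))
    stop("duplicate categories in selection", call. = FALSE)
  selection <- selection[selection != "sampleLabel"]
  if (!length(selection)) stop("empty selection", call. = FALSE)
  registry <- defaultCategories()
  unknown <- setdiff(selection, names(registry))
  if (length(unknown))
    stop(sprintf("unknown categories: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  coreTypes <- c("species", "organ", "cellLine", "material")
  if (!any(selection %in% coreTypes))
    stop("at least one core sample type is required (species, organ, ",
         "cellLine or material)", call. = FALSE)
  for (unit in intersect(selection, names(unitMagnitudePairs))) {
    if (!unitMagnitudePairs[[unit]] %in% selection)
      stop(sprintf("'%s' requires its magnitude partner '%s'",
                   unit, unitMagnitudePairs[[unit]]), call. = FALSE)
  }
  specs <- registry[selection]
  groupOf <- vapply(specs, function(x) x@grouping, character(1))
  ordered <- unlist(lapply(categoryGroupings, function(g)
    selection[groupOf == g]), use.names = FALSE)
  submissionMatrix(c(list(registry[["sampleLabel"]]), registry[ordered]))
}

#' Export a schema as JSON
#'
#' The machine-readable companion of a matrix template: the ordered category
#' list with groupings and value classes.
#'
#' @param x a \linkS4class{SubmissionMatrix}.
#' @param path optional file; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
schemaJSON <- function(x, path = NULL) {
  entries <- lapply(x@categories, function(cs)
    list(name = cs@name, grouping = cs@grouping,
         value_class = cs@valueClass))
  json <- jsonlite::toJSON(unname(entries), auto_unbox = TRUE,
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read / write a submission matrix as CSV
#'
#' RFC 4180 CSV, UTF-8, header row of registered category names. Cell text
#' is passed through verbatim -- normalization happens during
#' standardization, which preserves the originals in the curation report.
#' \code{readSubmission(writeSubmission(m))} reproduces the matrix exactly,
#' empty cells included. Unknown headers, duplicate headers, a missing
#' sampleLabel column and ragged rows are errors.
#'
#' @param path CSV file path.
#' @param categories registry of known categories (named list of
#'   \linkS4class{CategorySpec}); defaults to the standard registry.
#' @param x a \linkS4class{SubmissionMatrix}.
#' @return \code{readSubmission}: a \linkS4class{SubmissionMatrix};
#'   \code{writeSubmission}: the path, invisibly.
#' @export
readSubmission <- function(path, categories = defaultCategories()) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  nf <- nf[!is.na(nf)]  # NA marks lines continued inside quotes
  if (length(nf) > 1L && any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])
    stop(sprintf("ragged row(s) at line(s) %s: expected %d fields",
                 paste(bad, collapse = ", "), nf[1L]), call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fill = FALSE,
                        na.strings = character(0), fileEncoding = "UTF-8")
  headers <- colnames(df)
  if (anyDuplicated(headers))
    stop(sprintf("duplicate headers: %s",
                 paste(unique(headers[duplicated(headers)]),
                       collapse = ", ")), call. = FALSE)
  unknown <- setdiff(headers, names(categories))
  if (length(unknown))
    stop(sprintf("unknown headers: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (!"sampleLabel" %in% headers)
    stop("missing sampleLabel column", call. = FALSE)
  blank <- which(!nzchar(df[["sampleLabel"]]))
  if (length(blank))
    stop(sprintf("empty sampleLabel in row(s) %s",
                 paste(blank, collapse = ", ")), call. = FALSE)
  submissionMatrix(categories[headers], df)
}

#' @rdname readSubmission
#' @export
writeSubmission <- function(x, path) {
  utils::write.csv(x@data, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", eol = "\n", quote = TRUE)
  invisible(path)
}
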
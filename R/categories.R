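#' Construct a CategorySpec
#'
#' @param name category identifier, e.g. "species".
#' @param grouping one of CoreSampleType, SampleDescription, StudyFactors,
#'   TimeSeries, Other.
#' @param valueClass one of controlled, numeric, freetext.
#' @return a \linkS4class{CategorySpec}.
#' @export
categorySpec <- function(name, grouping, valueClass) {
  new("CategorySpec", name = name, grouping = grouping,
      valueClass = valueClass)
}

# The registry of standard metadata categories: the four core sample types,
# sample descriptors with their unit/magnitude pairs, study factors, the
# time-series pair, and the freetext escape hatches. Unit categories are tied
# to their magnitude partner for schema validation.
categoryTable <- function() {
  tab <- rbind(
    c("sampleLabel",       "Other",             "freetext"),
    c("species",           "CoreSampleType",    "controlled"),
    c("organ",             "CoreSampleType",    "controlled"),
    c("cellLine",          "CoreSampleType",    "controlled"),
    c("material",          "CoreSampleType",    "controlled"),
    c("mass",              "SampleDescription", "numeric"),
    c("massUnit",          "SampleDescription", "controlled"),
    c("volume",            "SampleDescription", "numeric"),
    c("volumeUnit",        "SampleDescription", "controlled"),
    c("sex",               "SampleDescription", "controlled"),
    c("height",            "SampleDescription", "numeric"),
    c("heightUnit",        "SampleDescription", "controlled"),
    c("weight",            "SampleDescription", "numeric"),
    c("weightUnit",        "SampleDescription", "controlled"),
    c("age",               "SampleDescription", "numeric"),
    c("ageUnit",           "SampleDescription", "controlled"),
    c("ethnicity",         "SampleDescription", "controlled"),
    c("geographicalOrigin","SampleDescription", "controlled"),
    c("strain",            "SampleDescription", "controlled"),
    c("drugName",          "StudyFactors",      "controlled"),
    c("drugDoseMagnitude", "StudyFactors",      "numeric"),
    c("drugDoseUnit",      "StudyFactors",      "controlled"),
    c("geneKnockout",      "StudyFactors",      "controlled"),
    c("disease",           "StudyFactors",      "controlled"),
    c("diet",              "StudyFactors",      "controlled"),
    c("exercise",          "StudyFactors",      "controlled"),
    c("zeroTimeEvent",     "TimeSeries",        "controlled"),
    c("time",              "TimeSeries",        "numeric"),
    c("timeUnit",          "TimeSeries",        "controlled"),
    c("inclusion",         "Other",             "freetext"),
    c("exclusion",         "Other",             "freetext"),
    c("comment",           "Other",             "freetext"))
  data.frame(name = tab[, 1], grouping = tab[, 2], valueClass = tab[, 3],
             stringsAsFactors = FALSE)
}

# unit category -> its magnitude partner (must co-occur in a schema)
unitMagnitudePairs <- c(
  massUnit = "mass", volumeUnit = "volume", heightUnit = "height",
  weightUnit = "weight", ageUnit = "age", timeUnit = "time",
  drugDoseUnit = "drugDoseMagnitude")

#' The standard metadata category registry
#'
#' Returns the specs of all standard categories: the core sample types
#' (species, organ, cellLine, material), the sample descriptors and their
#' unit/magnitude pairs, the study factors, the time-series trio, and the
#' freetext categories (sampleLabel, inclusion, exclusion, comment).
#'
#' @return named list of \linkS4class{CategorySpec}.
#' @export
defaultCategories <- function() {
  tab <- categoryTable()
  specs <- lapply(seq_len(nrow(tab)), function(i)
    categorySpec(tab$name[i], tab$grouping[i], tab$valueClass[i]))
  names(specs) <- tab$name
  specs
}

#' @describeIn defaultCategories spec of one standard category by name.
#' @param name category name.
#' @export
standardCategory <- function(name) {
  cats <- defaultCategories()
  if (!name %in% names(cats))
    stop(sprintf("unknown category '%s'", name), call. = FALSE)
  cats[[name]]
}

#' Accessors for CategorySpec
#' @param x a \linkS4class{CategorySpec}.
#' @return the slot value.
#' @export
categoryName <- function(x) x@name

#' @rdname categoryName
#' @export
categoryGrouping <- function(x) x@grouping

#' @rdname categoryName
#' @export
categoryValueClass <- function(x) x@valueClass
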
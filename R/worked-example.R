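#' The ozone-exposure worked example
#'
#' A complete end-to-end fixture modeled on a lung-metabolism study in which
#' mice were exposed to house dust mite allergen and then to ozone: a
#' freetext submission matrix over the header set (sampleLabel, organ, mass,
#' massUnit, species, sex, age, ageUnit, strain, drugName,
#' drugDoseMagnitude, drugDoseUnit, zeroTimeEvent, time, timeUnit) and a
#' vocabulary store that already contains main terms or synonyms for every
#' controlled value EXCEPT three strings -- "allergen exposure"
#' (zeroTimeEvent), "ozone" (drugName) and "hours/day" (drugDoseUnit) --
#' which the three-pass pipeline must surface as new-term candidates and,
#' once confirmed, adopt into their vocabularies.
#'
#' The parts of this fixture anchored to the original study description are
#' the header set, the "mouse" -> "mus musculus" synonym mapping and the
#' three new terms; the numeric magnitudes (masses, ages, doses, times) are
#' synthetic placeholders, and the store's other terms are a plausible
#' synthetic subset of the real ontology-derived vocabularies.
#'
#' @return list with \code{matrix} (the freetext
#'   \linkS4class{SubmissionMatrix}), \code{store} (the
#'   \linkS4class{VocabularyStore}), \code{confirmations} (the
#'   \linkS4class{ConfirmationSet} adopting the three new terms), and
#'   \code{expectedNewTerms} (data.frame of category/term pairs expected to
#'   be added).
#' @examples
#' wex <- workedExample()
#' res <- standardize(wex$matrix, wex$store,
#'                    confirmations = wex$confirmations)
#' matrixData(res$matrix)$species  # all "mus musculus"
#' @export
workedExample <- function() {
  store <- vocabularyStore(list(
    vocabulary("organ",
               c("lung", "liver", "brain", "heart", "kidney"),
               c("pulmonary tissue" = "lung", "lungs" = "lung")),
    vocabulary("species",
               c("mus musculus", "homo sapiens", "rattus norvegicus"),
               c(mouse = "mus musculus", mice = "mus musculus",
                 "house mouse" = "mus musculus",
                 rat = "rattus norvegicus", human = "homo sapiens")),
    vocabulary("sex", c("male", "female", "hermaphrodite")),
    vocabulary("massUnit", c("gram", "milligram", "kilogram"),
               c(grams = "gram", milligrams = "milligram", mg = "milligram",
                 g = "gram")),
    vocabulary("ageUnit", c("week", "month", "year"),
               c(weeks = "week", months = "month", years = "year")),
    vocabulary("strain", c("balb/c", "c57bl/6", "dba/2"),
               c("c57 black 6" = "c57bl/6")),
    vocabulary("drugName",
               c("dexamethasone", "ibuprofen", "acetaminophen"),
               c(paracetamol = "acetaminophen")),
    vocabulary("drugDoseUnit",
               c("milligram per kilogram", "part per million"),
               c("mg/kg" = "milligram per kilogram",
                 ppm = "part per million")),
    vocabulary("zeroTimeEvent",
               c("birth", "treatment start", "inoculation"),
               c("start of treatment" = "treatment start")),
    vocabulary("timeUnit", c("hour", "day", "minute", "second"),
               c(hours = "hour", days = "day", h = "hour"))),
    categories = NULL)
  # register the numeric partners and sampleLabel alongside
  registry <- defaultCategories()
  cats <- store@categories
  for (nm in c("mass", "age", "drugDoseMagnitude", "time"))
    cats[[nm]] <- registry[[nm]]
  store <- new("VocabularyStore", categories = cats,
               vocabularies = store@vocabularies)

  template <- buildSchema(c(
    "organ", "species", "mass", "massUnit", "sex", "age", "ageUnit",
    "strain", "drugName", "drugDoseMagnitude", "drugDoseUnit",
    "zeroTimeEvent", "time", "timeUnit"))
  header <- names(template@categories)
  rows <- list(
    c("ozone_m_1", "Lung", "mouse",   "118", "mg", "Male",   "8",
      "weeks", "BALB/c", "ozone", "0.5", "hours/day",
      "allergen exposure", "24", "hours"),
    c("ozone_f_1", "lungs", "Mouse",  "102", "mg", "female", "8",
      "weeks", "BALB/c", "ozone", "0.5", "hours/day",
      "allergen exposure", "24", "hours"),
    c("control_m_1", "Lung", "mice",  "121", "mg", "male",   "8",
      "weeks", "BALB/c", "", "", "",
      "allergen exposure", "24", "hours"),
    c("control_f_1", "lung", "house mouse", "99", "mg", "Female", "8",
      "weeks", "BALB/c", "", "", "",
      "allergen exposure", "24", "hours"))
  rowOrder <- c("sampleLabel", "organ", "species", "mass", "massUnit",
                "sex", "age", "ageUnit", "strain", "drugName",
                "drugDoseMagnitude", "drugDoseUnit", "zeroTimeEvent",
                "time", "timeUnit")
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(df) <- rowOrder
  df <- df[header]
  m <- submissionMatrix(template@categories, df)

  conf <- confirmationSet()
  conf <- confirmNewTerm(conf, "zeroTimeEvent", "allergen exposure")
  conf <- confirmNewTerm(conf, "drugName", "ozone")
  conf <- confirmNewTerm(conf, "drugDoseUnit", "hours/day")

  list(matrix = m, store = store, confirmations = conf,
       expectedNewTerms = data.frame(
         category = c("zeroTimeEvent", "drugName", "drugDoseUnit"),
         term = c("allergen exposure", "ozone", "hours/day"),
         stringsAsFactors = FALSE))
}
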
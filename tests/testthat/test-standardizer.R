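test_that("classifyCell returns the category's value class", {
  wex <- workedExample()
  expect_identical(classifyCell(wex$store, "species"), "controlled")
  expect_identical(classifyCell(wex$store, "drugDoseMagnitude"), "numeric")
  expect_identical(classifyCell(wex$store, "sampleLabel"), "freetext")
  expect_error(classifyCell(wex$store, "favoriteColor"), "unknown category")
})

test_that("pass 1 resolves, validates and records empties", {
  store <- tinyStore(extra = "age")
  models <- fitModels(store)
  cats <- storeCategories(store)
  m <- submissionMatrix(
    cats[c("sampleLabel", "species", "age")],
    data.frame(sampleLabel = c("s1", "s2"),
               species = c("mouse", ""),
               age = c("10", "1.5e2")))
  work <- pass1Auto(m, store, models)
  syn <- work[work$category == "species" & work$row == 1, ]
  expect_identical(syn$pass, "synonym")
  expect_identical(syn$final, "mus musculus")
  expect_equal(syn$similarity, 1.0)
  expect_identical(work[work$category == "species" & work$row == 2, ]$pass,
                   "empty")
  expect_identical(work[work$category == "age", ]$pass,
                   c("passthrough", "passthrough"))
  # bad numerics stop with row and category
  bad <- submissionMatrix(
    cats[c("sampleLabel", "species", "age")],
    data.frame(sampleLabel = "s1", species = "mouse", age = "1,5"))
  expect_error(pass1Auto(bad, store, models),
               "row 1, category 'age'")
})

test_that("pass 2 proposes substring hits only for unresolved values", {
  store <- tinyStore()
  models <- fitModels(store)
  cats <- storeCategories(store)
  # "musc" shares too few trigrams with "mus musculus" to auto-apply, and
  # "mu" (shorter than a trigram) shares none at all -- both are rescued by
  # the substring search; "xqzw" is beyond rescue
  m <- submissionMatrix(
    cats[c("sampleLabel", "species")],
    data.frame(sampleLabel = c("s1", "s2", "s3", "s4"),
               species = c("musc", "xqzw", "mouse", "mu")))
  work <- pass2Substring(pass1Auto(m, store, models), store)
  sub <- work[work$original == "musc", ]
  expect_identical(sub$status, "proposed")
  cand <- attr(work, "candidates")[[which(work$original == "musc")]]
  expect_true("mus musculus" %in% cand$surface[cand$source == "substring"])
  # a value with no trigram overlap gets its only candidates from pass 2
  cand2 <- attr(work, "candidates")[[which(work$original == "mu")]]
  expect_true(all(cand2$source == "substring"))
  expect_identical(work[work$original == "mu", ]$status, "proposed")
  expect_identical(work[work$original == "xqzw", ]$status, "unmatched")
  # values resolved in pass 1 stay untouched
  expect_identical(work[work$original == "mouse", ]$pass, "synonym")
})

test_that("pass 3 requires confirmations and applies them by provenance", {
  store <- tinyStore()
  cats <- storeCategories(store)
  m <- submissionMatrix(
    cats[c("sampleLabel", "species", "drugName")],
    data.frame(sampleLabel = "s1", species = "mu",
               drugName = "ozone"))
  # no confirmations: pending condition enumerating both values
  err <- tryCatch(standardize(m, store), metacurate_pending = identity)
  expect_s3_class(err, "metacurate_pending")
  pend <- pendingValues(err)
  expect_setequal(pend$original, c("mu", "ozone"))
  # substring proposal accepted; ozone adopted as a new term
  conf <- confirmProposal(confirmationSet(), "species", "mu",
                          "mus musculus")
  conf <- confirmNewTerm(conf, "drugName", "ozone")
  res <- standardize(m, store, confirmations = conf)
  e <- reportEntries(res$report)
  expect_identical(e[e$original == "mu", ]$pass, "substring")
  expect_identical(e[e$original == "mu", ]$final, "mus musculus")
  expect_identical(e[e$original == "ozone", ]$pass, "new_term")
  expect_true("ozone" %in% mainTerms(getVocabulary(res$store, "drugName")))
  # accepted proposals never mutate the vocabulary
  expect_identical(vocabVersion(getVocabulary(res$store, "species")),
                   vocabVersion(getVocabulary(store, "species")))
  # a proposal naming a non-candidate is rejected
  confBad <- confirmProposal(confirmationSet(), "species", "mu",
                             "arabidopsis thaliana")
  confBad <- confirmNewTerm(confBad, "drugName", "ozone")
  expect_error(standardize(m, store, confirmations = confBad),
               "not a candidate")
})

test_that("mid-band nearest-neighbor proposals resolve as nn_confirmed", {
  store <- vocabularyStore(vocabulary(
    "species", c("mus musculus", "arabidopsis thaliana")))
  cats <- storeCategories(store)
  m <- submissionMatrix(
    cats[c("sampleLabel", "species")],
    data.frame(sampleLabel = "s1", species = "ulus fragment"))
  conf <- confirmProposal(confirmationSet(), "species", "ulus fragment",
                          "mus musculus")
  res <- standardize(m, store, confirmations = conf)
  e <- reportEntries(res$report)
  expect_identical(e[e$original == "ulus fragment", ]$pass, "nn_confirmed")
  expect_equal(e[e$original == "ulus fragment", ]$similarity, 0.5,
               tolerance = 1e-9)
})

test_that("new terms clashing with another category are refused", {
  store <- tinyStore()
  cats <- storeCategories(store)
  m <- submissionMatrix(
    cats[c("sampleLabel", "drugName")],
    data.frame(sampleLabel = "s1", drugName = "arabidopsis thaliana"))
  conf <- confirmNewTerm(confirmationSet(), "drugName",
                         "arabidopsis thaliana")
  expect_error(standardize(m, store, confirmations = conf),
               "orthogonality.*species")
})

test_that("multi-value cells are curated per value and rejoined", {
  store <- tinyStore()
  cats <- storeCategories(store)
  m <- submissionMatrix(
    cats[c("sampleLabel", "species")],
    data.frame(sampleLabel = "s1",
               species = "mouse; arabidopsis thaliana"))
  res <- standardize(m, store)
  expect_identical(matrixData(res$matrix)$species,
                   "mus musculus;arabidopsis thaliana")
  e <- reportEntries(res$report)
  expect_identical(nrow(e[e$category == "species", ]), 2L)
  expect_identical(e[e$category == "species", ]$valueIndex, 1:2)
})

test_that("the worked example plays out end to end", {
  wex <- workedExample()
  # passes 1-2 leave exactly the three known strings unresolved
  pend <- tryCatch(standardize(wex$matrix, wex$store),
                   metacurate_pending = pendingValues)
  expect_setequal(pend$original,
                  c("allergen exposure", "ozone", "hours/day"))
  res <- standardize(wex$matrix, wex$store,
                     confirmations = wex$confirmations)
  for (i in seq_len(nrow(wex$expectedNewTerms))) {
    expect_true(wex$expectedNewTerms$term[i] %in%
      mainTerms(getVocabulary(res$store, wex$expectedNewTerms$category[i])))
  }
  expect_true(all(matrixData(res$matrix)$species == "mus musculus"))
  expect_identical(nrow(metacurate:::guaranteeViolations(res$store,
                                                         res$matrix)), 0L)
  # second run is the identity with exact/passthrough/empty passes only
  res2 <- standardize(res$matrix, res$store, res$models)
  expect_identical(matrixData(res2$matrix), matrixData(res$matrix))
  ctrl <- reportEntries(res2$report)
  ctrl <- ctrl[vapply(ctrl$category, function(c)
    classifyCell(res$store, c) == "controlled", TRUE), ]
  expect_true(all(ctrl$pass %in% c("exact", "empty")))
})

test_that("standardization is deterministic and all-or-nothing", {
  store <- generateVocabularyStore(fixtureConfig(seed = 9, nTerms = 12),
                                   c("species", "organ"))
  m <- generateSubmissionMatrix(store, nRows = 6, seed = 14,
                                junkRate = 0.2)
  conf <- autoConfirmations(m, store)
  a <- standardize(m, store, confirmations = conf)
  b <- standardize(m, store, confirmations = conf)
  expect_identical(matrixData(a$matrix), matrixData(b$matrix))
  expect_identical(reportEntries(a$report), reportEntries(b$report))
  # a failing run must not have mutated the store (fresh pending error)
  m2 <- generateSubmissionMatrix(store, nRows = 4, seed = 15,
                                 junkRate = 0.5)
  before <- vapply(store@vocabularies, vocabVersion, 1L)
  try(standardize(m2, store), silent = TRUE)
  expect_identical(vapply(store@vocabularies, vocabVersion, 1L), before)
})

test_that("guarantee and idempotence hold across seeded random matrices", {
  store0 <- generateVocabularyStore(
    fixtureConfig(seed = 2, nTerms = 15, synonymRate = 0.4),
    c("species", "organ", "drugName"))
  for (seed in 101:110) {
    m <- generateSubmissionMatrix(store0, nRows = 4, seed = seed,
                                  junkRate = 0.15)
    conf <- autoConfirmations(m, store0)
    res <- standardize(m, store0, confirmations = conf)
    expect_identical(
      nrow(metacurate:::guaranteeViolations(res$store, res$matrix)), 0L)
    res2 <- standardize(res$matrix, res$store, res$models)
    expect_identical(matrixData(res2$matrix), matrixData(res$matrix))
    expect_identical(vapply(res2$store@vocabularies, vocabVersion, 1L),
                     vapply(res$store@vocabularies, vocabVersion, 1L))
    # report covers every delimited value plus empties
    vals <- sum(vapply(seq_len(nSamples(m)), function(ri)
      sum(vapply(names(matrixCategories(m)), function(cat) {
        cell <- matrixData(m)[ri, cat]
        max(1L, length(metacurate:::splitCell(cell)))
      }, 1L)), 1L))
    expect_identical(nrow(reportEntries(res$report)), vals)
  }
})
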
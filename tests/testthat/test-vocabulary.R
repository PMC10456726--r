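test_that("normalizeString lowercases, trims and collapses whitespace", {
  expect_identical(normalizeString("  Mus   Musculus "), "mus musculus")
  expect_identical(normalizeString("OZONE"), "ozone")
  expect_identical(normalizeString("mus musculus"), "mus musculus")
  expect_identical(normalizeString(""), "")
  expect_identical(normalizeString("a\t b\n c"), "a b c")
})

test_that("lookup resolves main terms, synonyms and misses", {
  store <- tinyStore()
  hit <- vocabLookup(store, "species", "mouse")
  expect_identical(hit$result, "synonym")
  expect_identical(hit$term, "mus musculus")
  expect_identical(vocabLookup(store, "species", "mus musculus")$result,
                   "main")
  expect_identical(vocabLookup(store, "species", "zzzz")$result, "miss")
  # lookup is a function of the normalized form
  expect_identical(vocabLookup(store, "species", "  MOUSE ")$term,
                   "mus musculus")
  expect_error(vocabLookup(store, "favoriteColor", "x"), "unknown category")
  expect_error(vocabLookup(store, "sampleLabel", "x"), "not controlled")
})

test_that("addMainTerm adds, is idempotent, and enforces orthogonality", {
  store <- tinyStore()
  v0 <- getVocabulary(store, "drugName")
  store2 <- addMainTerm(store, "drugName", "ozone")
  v2 <- getVocabulary(store2, "drugName")
  expect_true("ozone" %in% mainTerms(v2))
  expect_identical(vocabVersion(v2), vocabVersion(v0) + 1L)
  # no-op re-add leaves the version alone
  store3 <- addMainTerm(store2, "drugName", "OZONE")
  expect_identical(vocabVersion(getVocabulary(store3, "drugName")),
                   vocabVersion(v2))
  # a species main term may not enter drugName
  expect_error(addMainTerm(store, "drugName", "mus musculus"),
               "orthogonality")
  expect_error(addMainTerm(store, "drugName", "   "), "non-empty")
})

test_that("promoting a synonym to main term drops the synonym entry", {
  store <- tinyStore()
  store2 <- addMainTerm(store, "species", "mouse")
  v <- getVocabulary(store2, "species")
  expect_true("mouse" %in% mainTerms(v))
  expect_false("mouse" %in% names(synonymMap(v)))
  expect_identical(nrow(validateStore(store2)), 0L)
})

test_that("addSynonym maps to existing mains and rejects redundancy", {
  store <- vocabularyStore(vocabulary("species", "mus musculus"))
  store <- addSynonym(store, "species", "House  Mouse", "mus musculus")
  expect_identical(vocabLookup(store, "species", "house mouse")$term,
                   "mus musculus")
  expect_error(addSynonym(store, "species", "mus musculus", "mus musculus"),
               "redundancy")
  expect_error(addSynonym(store, "species", "mice", "canis lupus"),
               "not a main term")
})

test_that("validateStore reports overlaps and redundancies", {
  expect_identical(nrow(validateStore(vocabularyStore())), 0L)
  expect_identical(nrow(validateStore(tinyStore())), 0L)
  # construct a cross-category overlap behind the validity method's back
  store <- tinyStore()
  v <- store@vocabularies[["drugName"]]
  slot(v, "mainTerms", check = FALSE) <- c(v@mainTerms, "homo sapiens")
  slot(store, "vocabularies", check = FALSE) <-
    modifyList(store@vocabularies, list(drugName = v))
  vs <- store@vocabularies[["species"]]
  slot(vs, "mainTerms", check = FALSE) <- c(vs@mainTerms, "homo sapiens")
  slot(store, "vocabularies", check = FALSE) <-
    modifyList(store@vocabularies, list(species = vs))
  viol <- validateStore(store)
  expect_identical(nrow(viol), 1L)
  expect_identical(viol$type, "orthogonality")
  expect_match(viol$categories, "species")
  expect_match(viol$categories, "drugName")
  expect_identical(viol$term, "homo sapiens")
})

test_that("random successful addMainTerm sequences keep the store valid", {
  store <- generateVocabularyStore(fixtureConfig(seed = 11, nTerms = 10),
                                   c("species", "organ", "drugName"))
  set.seed(99)
  cats <- controlledCategories(store)
  for (i in 1:40) {
    term <- paste0("added", i, " ",
                   paste(sample(letters, 5, TRUE), collapse = ""))
    store <- addMainTerm(store, sample(cats, 1), term)
    expect_identical(nrow(validateStore(store)), 0L)
  }
  # every cross-category re-add of an existing main term must fail
  for (cat in cats) {
    other <- setdiff(cats, cat)[1L]
    term <- mainTerms(getVocabulary(store, cat))[1L]
    expect_error(addMainTerm(store, other, term), "orthogonality")
  }
})

test_that("vocabulary TSV round-trips field for field", {
  for (seed in c(1, 7, 23)) {
    v <- generateVocabulary(fixtureConfig(seed = seed, nTerms = 12,
                                          synonymRate = 0.8), "species")
    p <- withr::local_tempfile(fileext = ".tsv")
    saveVocab(v, p)
    v2 <- loadVocab(p, "species", version = vocabVersion(v))
    expect_identical(mainTerms(v2), mainTerms(v))
    expect_identical(synonymMap(v2), synonymMap(v))
    expect_identical(vocabVersion(v2), vocabVersion(v))
  }
})

test_that("TSV parse errors carry line numbers", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\trole\tmaps_to", "mus musculus\tmain\t",
               "mouse\tother\tmus musculus"), p)
  expect_error(loadVocab(p, "species"), ":3: malformed role")
  writeLines(c("term\trole\tmaps_to", "mouse\tsynonym\tmus musculus"), p)
  expect_error(loadVocab(p, "species"), "dangling maps_to")
  writeLines(c("term\trole\tmaps_to", "mus musculus\tmain\t",
               "mus musculus\tmain\t"), p)
  expect_error(loadVocab(p, "species"), ":3: duplicate term")
  writeLines(c("bad\theader"), p)
  expect_error(loadVocab(p, "species"), ":1: header")
})

test_that("a synonym TSV row loads as a synonym entry", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\trole\tmaps_to", "mus musculus\tmain\t",
               "mouse\tsynonym\tmus musculus"), p)
  v <- loadVocab(p, "species")
  expect_identical(unname(synonymMap(v)["mouse"]), "mus musculus")
})

test_that("store directory persistence round-trips with the manifest", {
  store <- generateVocabularyStore(fixtureConfig(seed = 4, nTerms = 6),
                                   c("species", "sex"))
  store <- addMainTerm(store, "species", "late addition")
  d <- withr::local_tempdir()
  saveStore(store, d)
  store2 <- loadStore(d)
  expect_identical(names(store2@vocabularies), names(store@vocabularies))
  for (nm in controlledCategories(store)) {
    expect_identical(mainTerms(getVocabulary(store2, nm)),
                     mainTerms(getVocabulary(store, nm)))
    expect_identical(vocabVersion(getVocabulary(store2, nm)),
                     vocabVersion(getVocabulary(store, nm)))
  }
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_setequal(vapply(manifest, `[[`, "", "name"),
                  names(storeCategories(store)))
})
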
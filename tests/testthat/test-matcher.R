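toyVocab <- function() {
  vocabulary("species", c("mus musculus", "arabidopsis thaliana"))
}

# independent per-pair tf-idf cosine for tiny cases, written from the
# definitions (raw count tf, ln((1+D)/(1+df)) + 1 idf, L2, dot product)
tinyCosine <- function(surfaces, query, n = 3L) {
  grams <- function(s) {
    if (nchar(s) < n) return(s)
    vapply(1:(nchar(s) - n + 1L), function(i) substr(s, i, i + n - 1L), "")
  }
  docs <- lapply(surfaces, function(s) table(grams(s)))
  vocab <- unique(unlist(lapply(docs, names)))
  df <- vapply(vocab, function(g)
    sum(vapply(docs, function(d) g %in% names(d), TRUE)), 0)
  idf <- log((1 + length(surfaces)) / (1 + df)) + 1
  names(idf) <- vocab
  vec <- function(tab) {
    keep <- intersect(names(tab), vocab)
    v <- stats::setNames(numeric(length(vocab)), vocab)
    v[keep] <- as.numeric(tab[keep]) * idf[keep]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }
  q <- vec(table(grams(query)))
  vapply(docs, function(d) sum(vec(d) * q), 0)
}

test_that("trigram extraction slides over spaces with multiplicity", {
  g <- extractNgrams("mus musculus")
  expect_length(g, 10)
  expect_true(all(c("mus", "us ", "s m", " mu", "usc") %in% g))
  expect_identical(sum(g == "mus"), 2L)
  expect_identical(extractNgrams("ab"), "ab")
  expect_identical(extractNgrams(""), character(0))
})

test_that("fitted dimensionality is the union of surface grams", {
  # disjoint grams add up
  v <- vocabulary("species", c("aaaa", "bbbb"))
  m <- fitTrigramModel(v)
  expect_length(m@componentIndex, 2L)  # "aaa" and "bbb"
  # single surface: uniform idf, unit norm
  m1 <- fitTrigramModel(vocabulary("species", "mus musculus"))
  expect_equal(length(unique(m1@idf)), 1L)
  expect_equal(sqrt(Matrix::rowSums(m1@surfaceMatrix^2)[1]), 1,
               tolerance = 1e-12)
})

test_that("refitting after a term addition extends the component space", {
  store <- vocabularyStore(vocabulary("drugName",
                                      c("dexamethasone", "ibuprofen")))
  m0 <- fitTrigramModel(getVocabulary(store, "drugName"))
  expect_false(any(c("ozo", "zon") %in% names(m0@componentIndex)))
  store <- addMainTerm(store, "drugName", "ozone")
  m1 <- fitTrigramModel(getVocabulary(store, "drugName"))
  expect_true(all(c("ozo", "zon", "one") %in% names(m1@componentIndex)))
  # the new term self-retrieves at 1.0
  r <- nearestTerm(m1, "ozone")
  expect_identical(matchDecisionOf(r), "auto")
  expect_equal(matchCandidates(r)$similarity[1], 1.0)
})

test_that("vectorize coerces into the fitted space", {
  m <- fitTrigramModel(toyVocab())
  # a vocabulary surface has cosine 1 with its own row
  v <- vectorizeTerm(m, "mus musculus")
  sims <- as.numeric(m@surfaceMatrix %*% v)
  expect_equal(max(sims), 1, tolerance = 1e-12)
  # no shared gram -> zero vector
  expect_identical(sum(vectorizeTerm(m, "qqqq")), 0)
})

test_that("nearest matches the independent tiny-case cosine", {
  m <- fitTrigramModel(toyVocab())
  surfaces <- c("mus musculus", "arabidopsis thaliana")
  for (q in c("mus musculuss", "ulus fragment", "arabidopsis t",
              "thaliana mus")) {
    want <- tinyCosine(surfaces, q)
    r <- nearestTerm(m, q)
    expect_identical(topTerm(r), surfaces[which.max(want)])
    expect_equal(matchCandidates(r)$similarity[1], max(want),
                 tolerance = 1e-9)
  }
  # the near-typo stays closer to its source than to the other term
  want <- tinyCosine(surfaces, "mus musculuss")
  expect_gt(want[1], want[2])
})

test_that("decisions follow the exact hit and threshold rules", {
  store <- tinyStore()
  m <- fitTrigramModel(getVocabulary(store, "species"))
  r <- nearestTerm(m, "mice")
  expect_identical(matchDecisionOf(r), "auto")
  expect_identical(topTerm(r), "mus musculus")
  expect_equal(matchCandidates(r)$similarity[1], 1.0)
  # zero-gram query is unmatched with no candidates
  r2 <- nearestTerm(m, "qqqq")
  expect_identical(matchDecisionOf(r2), "unmatched")
  expect_identical(nrow(matchCandidates(r2)), 0L)
  # mid-band similarity is proposed: enumerated by hand, 'ulus fragment'
  # shares exactly {ulu, lus, 'us '} with 'mus musculus' giving cosine
  # 3 / (sqrt(3) * sqrt(12)) = 0.5 under uniform idf
  m3 <- fitTrigramModel(toyVocab())
  r3 <- nearestTerm(m3, "ulus fragment")
  expect_identical(matchDecisionOf(r3), "proposed")
  expect_equal(matchCandidates(r3)$similarity[1], 0.5, tolerance = 1e-9)
})

test_that("model and brute-force oracle agree query by query", {
  v <- generateVocabulary(fixtureConfig(seed = 13, nTerms = 60,
                                        synonymRate = 0.4), "organ")
  m <- fitTrigramModel(v)
  set.seed(77)
  terms <- mainTerms(v)
  queries <- c(sample(terms, 40, replace = TRUE),
               unlist(lapply(sample(terms, 40, replace = TRUE), function(t)
                 generateTypos(t, 1, edits = 1,
                               seed = sample.int(1e6, 1)))),
               replicate(40, paste0(sample(letters, 7, TRUE),
                                    collapse = "")))
  nn <- nearestTerm(m, queries)
  bf <- bruteForceNearest(v, queries)
  for (i in seq_along(queries)) {
    expect_identical(topTerm(nn[[i]]), topTerm(bf[[i]]))
    expect_identical(matchDecisionOf(nn[[i]]), matchDecisionOf(bf[[i]]))
    ca <- matchCandidates(nn[[i]]); cb <- matchCandidates(bf[[i]])
    if (nrow(ca)) {
      expect_lt(abs(ca$similarity[1] - cb$similarity[1]), 1e-9)
      expect_true(all(ca$similarity >= 0 & ca$similarity <= 1))
      expect_true(all(diff(round(ca$similarity, 12)) <= 0))
    }
  }
})

test_that("every surface self-retrieves its main term at similarity 1", {
  v <- generateVocabulary(fixtureConfig(seed = 21, nTerms = 30,
                                        synonymRate = 0.5), "strain")
  m <- fitTrigramModel(v)
  surfaces <- c(mainTerms(v), names(synonymMap(v)))
  res <- nearestTerm(m, surfaces)
  for (i in seq_along(surfaces)) {
    expect_identical(matchDecisionOf(res[[i]]), "auto")
    expect_equal(matchCandidates(res[[i]])$similarity[1], 1.0)
    expected <- if (surfaces[i] %in% mainTerms(v)) surfaces[i]
                else unname(synonymMap(v)[surfaces[i]])
    expect_identical(topTerm(res[[i]]), expected)
  }
})

test_that("typo recovery is measured identically by model and oracle", {
  v <- generateVocabulary(fixtureConfig(seed = 31, nTerms = 80), "diet")
  m <- fitTrigramModel(v)
  set.seed(8)
  long <- mainTerms(v)[nchar(mainTerms(v)) >= 8]
  picked <- sample(long, 30)
  typos <- vapply(seq_along(picked), function(i)
    generateTypos(picked[i], 1, edits = 1, seed = 1000 + i), "")
  hitModel <- vapply(seq_along(typos), function(i)
    identical(topTerm(nearestTerm(m, typos[i])), picked[i]), TRUE)
  hitOracle <- vapply(seq_along(typos), function(i)
    identical(topTerm(bruteForceNearest(v, typos[i])), picked[i]), TRUE)
  expect_identical(hitModel, hitOracle)
  expect_gt(mean(hitModel), 0.8)  # reported metric, not a tuned threshold
})

test_that("substring search finds containments in both directions", {
  v <- vocabulary("species", c("mus musculus", "escherichia coli"))
  hits <- substringMatch(v, "musculus")
  expect_identical(hits$term[1], "mus musculus")
  expect_identical(hits$direction[1], "query_in_surface")
  hits2 <- substringMatch(v, "escherichia coli k12")
  expect_identical(hits2$term[1], "escherichia coli")
  expect_identical(hits2$direction[1], "surface_in_query")
  expect_identical(nrow(substringMatch(v, "zzz")), 0L)
  expect_error(substringMatch(v, "  "), "empty query")
})

test_that("serialized models answer queries identically", {
  v <- generateVocabulary(fixtureConfig(seed = 3, nTerms = 25,
                                        synonymRate = 0.3), "disease")
  m <- fitTrigramModel(v)
  p <- withr::local_tempfile(fileext = ".json")
  saveModel(m, p)
  m2 <- loadModel(p)
  expect_identical(m2@vocabVersion, m@vocabVersion)
  set.seed(6)
  for (q in c(sample(mainTerms(v), 3),
              generateTypos(mainTerms(v)[1], 2, seed = 2), "random junk")) {
    a <- nearestTerm(m, q); b <- nearestTerm(m2, q)
    expect_identical(matchCandidates(a)$term, matchCandidates(b)$term)
    expect_equal(matchCandidates(a)$similarity,
                 matchCandidates(b)$similarity, tolerance = 1e-12)
  }
})

test_that("stale models are refused by the pipeline", {
  store <- tinyStore()
  models <- fitModels(store)
  store2 <- addMainTerm(store, "drugName", "ozone")
  expect_false(modelCurrent(models[["drugName"]], store2))
  m <- submissionMatrix(
    storeCategories(store2)[c("sampleLabel", "drugName")],
    data.frame(sampleLabel = "s1", drugName = "ibuprofen"))
  expect_error(pass1Auto(m, store2, models), "retrain required")
})
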
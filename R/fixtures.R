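# Seeded evaluation that leaves the caller's RNG stream untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fixture generator configuration
#'
#' Settings for the synthetic vocabularies and matrices used throughout the
#' test suite. Identical config and seed give byte-identical fixtures.
#'
#' @param seed integer RNG seed.
#' @param nTerms main terms per generated vocabulary.
#' @param synonymRate expected synonyms per main term.
#' @param minSyllables,maxSyllables word length range (in
#'   consonant-vowel syllables).
#' @param wordsPerTerm words per generated term.
#' @return a plain list of settings.
#' @export
fixtureConfig <- function(seed = 1L, nTerms = 50L, synonymRate = 0.3,
                          minSyllables = 2L, maxSyllables = 4L,
                          wordsPerTerm = 2L) {
  list(seed = as.integer(seed), nTerms = as.integer(nTerms),
       synonymRate = synonymRate, minSyllables = as.integer(minSyllables),
       maxSyllables = as.integer(maxSyllables),
       wordsPerTerm = as.integer(wordsPerTerm))
}

fixtureConsonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r",
                       "s", "t", "v", "z")
fixtureVowels <- c("a", "e", "i", "o", "u")

randomWord <- function(minSyllables, maxSyllables) {
  k <- sample(minSyllables:maxSyllables, 1L)
  paste0(paste0(sample(fixtureConsonants, k, replace = TRUE),
                sample(fixtureVowels, k, replace = TRUE)),
         collapse = "")
}

# distinct 2-syllable prefixes, one per category index
categoryPrefix <- function(i) {
  c1 <- fixtureConsonants[((i - 1L) %% length(fixtureConsonants)) + 1L]
  v1 <- fixtureVowels[(((i - 1L) %/% length(fixtureConsonants)) %%
                        length(fixtureVowels)) + 1L]
  paste0(c1, v1, "x")
}

#' Generate a synthetic vocabulary
#'
#' Pronounceable multi-word lowercase terms, pairwise distinct. Each term's
#' first word starts with a category-specific prefix, so vocabularies
#' generated with different prefixes are orthogonal by construction.
#' Synonyms are generated at the configured rate (they carry the same
#' prefix; cross-category synonym collisions are permitted by design).
#'
#' @param config a \code{\link{fixtureConfig}}.
#' @param category target \linkS4class{CategorySpec} or standard category
#'   name.
#' @param prefix term prefix (default derived from the config seed).
#' @return a \linkS4class{Vocabulary}.
#' @export
generateVocabulary <- function(config = fixtureConfig(), category,
                               prefix = categoryPrefix(1L)) {
  withSeed(config$seed, {
    mains <- character(0)
    while (length(mains) < config$nTerms) {
      words <- vapply(seq_len(config$wordsPerTerm), function(i)
        randomWord(config$minSyllables, config$maxSyllables), character(1))
      words[1L] <- paste0(prefix, words[1L])
      term <- paste(words, collapse = " ")
      if (!term %in% mains) mains <- c(mains, term)
    }
    nSyn <- stats::rpois(length(mains), config$synonymRate)
    synKeys <- character(0); synVals <- character(0)
    for (i in seq_along(mains)) {
      made <- 0L
      while (made < nSyn[i]) {
        syn <- paste0(prefix, randomWord(config$minSyllables,
                                         config$maxSyllables))
        if (!syn %in% mains && !syn %in% synKeys) {
          synKeys <- c(synKeys, syn)
          synVals <- c(synVals, mains[i])
          made <- made + 1L
        }
      }
    }
    vocabulary(category, mains, stats::setNames(synVals, synKeys))
  })
}

#' Generate a store of orthogonal synthetic vocabularies
#'
#' @param config a \code{\link{fixtureConfig}}.
#' @param categories character vector of controlled standard category names.
#' @return a \linkS4class{VocabularyStore}; passes
#'   \code{\link{validateStore}} by construction (distinct prefixes).
#' @export
generateVocabularyStore <- function(config = fixtureConfig(),
                                    categories = c("species", "organ")) {
  vocabs <- lapply(seq_along(categories), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    generateVocabulary(cfg, categories[[i]], prefix = categoryPrefix(i))
  })
  vocabularyStore(vocabs)
}

applyEdit <- function(s, op) {
  chars <- strsplit(s, "")[[1L]]
  n <- length(chars)
  alphabet <- c(fixtureConsonants, fixtureVowels)
  if (op == "substitute") {
    i <- sample(n, 1L)
    repl <- sample(setdiff(alphabet, chars[i]), 1L)
    chars[i] <- repl
  } else if (op == "delete") {
    chars <- chars[-sample(n, 1L)]
  } else if (op == "insert") {
    i <- sample(n + 1L, 1L)
    chars <- append(chars, sample(alphabet, 1L), after = i - 1L)
  } else if (op == "transpose") {
    i <- sample(n - 1L, 1L)
    chars[c(i, i + 1L)] <- chars[c(i + 1L, i)]
  } else stop("unknown edit op: ", op, call. = FALSE)
  paste(chars, collapse = "")
}

#' Generate seeded typo variants of a term
#'
#' Applies random single-character edits (substitute, delete, insert) and
#' keeps only variants whose Levenshtein distance from the term equals
#' exactly \code{edits} (verified with \code{utils::adist}), so the corpus
#' is usable as ground truth for typo-tolerance measurements.
#'
#' @param term the source term (length >= 2).
#' @param n number of variants.
#' @param edits edit distance of each variant (default 1).
#' @param seed RNG seed.
#' @param ops edit operations to draw from.
#' @return character vector of \code{n} corrupted strings.
#' @export
generateTypos <- function(term, n = 1L, edits = 1L, seed = 1L,
                          ops = c("substitute", "delete", "insert")) {
  if (nchar(term) < 2L) stop("term too short to corrupt", call. = FALSE)
  if (edits == 0L) return(rep(term, n))
  withSeed(seed, {
    out <- character(0)
    guard <- 0L
    while (length(out) < n && guard < 1000L * n) {
      guard <- guard + 1L
      cand <- term
      for (e in seq_len(edits))
        cand <- applyEdit(cand, sample(ops, 1L))
      if (as.integer(utils::adist(term, cand)) == edits)
        out <- c(out, cand)
    }
    if (length(out) < n)
      stop("could not generate enough variants at the requested distance",
           call. = FALSE)
    out
  })
}

#' The species-rule ontology fixture (taxdump dialect)
#'
#' An 18-node ranked taxonomy written as taxdump-style node and name tables,
#' constructed so that each of the six species exclusion rules removes at
#' least one node: a rank-"strain" node, an "environmental samples" node with
#' a child, an "unclassified" node with a child, a "no rank" node containing
#' "/", a species containing digits, and a species containing "vector" --
#' plus six clean species with common-name synonyms. The expected survivor
#' set under the full rule list is recorded alongside.
#'
#' @param dir directory to write \code{nodes.dmp} and \code{names.dmp} into.
#' @return list with \code{nodesPath}, \code{namesPath}, \code{spec} (the
#'   \linkS4class{ExtractionSpec} with all six rules rooted at node 1), and
#'   \code{expectedSurvivors} (normalized names surviving the rules,
#'   hand-derived).
#' @export
speciesRuleFixture <- function(dir = tempfile("speciesfix")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes <- c(
    "1\t|\t1\t|\tno rank\t|",
    "2\t|\t1\t|\tgenus\t|",
    "3\t|\t2\t|\tspecies\t|",
    "4\t|\t1\t|\tgenus\t|",
    "5\t|\t4\t|\tspecies\t|",
    "6\t|\t5\t|\tstrain\t|",
    "7\t|\t1\t|\tno rank\t|",
    "8\t|\t7\t|\tspecies\t|",
    "9\t|\t2\t|\tno rank\t|",
    "10\t|\t9\t|\tspecies\t|",
    "11\t|\t1\t|\tno rank\t|",
    "12\t|\t2\t|\tspecies\t|",
    "13\t|\t4\t|\tspecies\t|",
    "14\t|\t15\t|\tspecies\t|",
    "15\t|\t1\t|\tgenus\t|",
    "16\t|\t1\t|\tspecies\t|",
    "17\t|\t1\t|\tspecies\t|",
    "18\t|\t1\t|\tspecies\t|")
  names <- c(
    "1\t|\troot\t|\tscientific name\t|",
    "2\t|\tFelis\t|\tscientific name\t|",
    "3\t|\tFelis catus\t|\tscientific name\t|",
    "3\t|\tcat\t|\tcommon name\t|",
    "3\t|\tdomestic cat\t|\tcommon name\t|",
    "4\t|\tMus\t|\tscientific name\t|",
    "5\t|\tMus musculus\t|\tscientific name\t|",
    "5\t|\tmouse\t|\tcommon name\t|",
    "5\t|\tmice\t|\tcommon name\t|",
    "5\t|\thouse mouse\t|\tcommon name\t|",
    "6\t|\tMus musculus C57BL/6J\t|\tscientific name\t|",
    "7\t|\tenvironmental samples\t|\tscientific name\t|",
    "8\t|\tuncultured bacterium\t|\tscientific name\t|",
    "9\t|\tunclassified Felis\t|\tscientific name\t|",
    "10\t|\tFelis sp. alpha\t|\tscientific name\t|",
    "11\t|\tcellular organisms/misc group\t|\tscientific name\t|",
    "12\t|\tinfluenza virus 2021\t|\tscientific name\t|",
    "13\t|\tcloning vector pbr\t|\tscientific name\t|",
    "14\t|\tCanis lupus\t|\tscientific name\t|",
    "14\t|\twolf\t|\tcommon name\t|",
    "15\t|\tCanis\t|\tscientific name\t|",
    "16\t|\tHomo sapiens\t|\tscientific name\t|",
    "16\t|\thuman\t|\tcommon name\t|",
    "17\t|\tArabidopsis thaliana\t|\tscientific name\t|",
    "17\t|\tthale cress\t|\tcommon name\t|",
    "18\t|\tDanio rerio\t|\tscientific name\t|",
    "18\t|\tzebrafish\t|\tcommon name\t|")
  nodesPath <- file.path(dir, "nodes.dmp")
  namesPath <- file.path(dir, "names.dmp")
  writeLines(nodes, nodesPath)
  writeLines(names, namesPath)
  spec <- extractionSpec("1", list(
    dropRank("strain"),
    dropDescendantsOfNameContaining("environmental sample"),
    dropDescendantsOfNameContaining("unclassified"),
    dropRankNameContaining("no rank", "/"),
    dropRankNameMatchingDigits("species"),
    dropRankNameContaining("species", "vector")))
  # hand-applied: 6 drops strain; 7+8 environmental-sample subtree; 9+10
  # unclassified subtree; 11 the '/' no-rank; 12 the digit species; 13 the
  # 'vector' species. Everything else survives.
  expectedSurvivors <- c(
    "root", "felis", "felis catus", "mus", "mus musculus", "canis",
    "canis lupus", "homo sapiens", "arabidopsis thaliana", "danio rerio")
  list(nodesPath = nodesPath, namesPath = namesPath, spec = spec,
       expectedSurvivors = expectedSurvivors)
}

#' The tree-number ontology fixture (heading dialect)
#'
#' A small descriptor table with dot-structured tree numbers, including a
#' multi-heading node parented under two branches, for exercising the
#' heading-prefix reader.
#'
#' @param dir directory to write \code{descriptors.tsv} into.
#' @return list with \code{path} and \code{expectedUnderA} (names of nodes
#'   at or under heading prefix "A").
#' @export
treeNumberFixture <- function(dir = tempfile("treenumfix")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lines <- c(
    "term\theadings\tsynonyms",
    "anatomy\tA\t",
    "body regions\tA01\tregions of the body",
    "head\tA01.456\t",
    "respiratory system\tA04\t",
    "lung\tA04.411\tpulmonary tissue;lungs",
    "neoplasms\tC04\ttumors",
    "neoplastic processes\tC04.697\t",
    "mixed node\tA01.911;C04.111\t")
  path <- file.path(dir, "descriptors.tsv")
  writeLines(lines, path)
  list(path = path,
       expectedUnderA = c("anatomy", "body regions", "head",
                          "respiratory system", "lung", "mixed node"))
}

#' Generate a random freetext submission matrix over a store
#'
#' Cells of controlled categories draw among exact main terms, synonyms,
#' seeded typo variants, case-mangled forms, novel junk strings, empties and
#' the occasional ";"-delimited multi-value; numeric categories get random
#' magnitudes and freetext categories short labels. Used by the
#' guarantee/idempotence property suite.
#'
#' @param store a \linkS4class{VocabularyStore}.
#' @param nRows sample count.
#' @param seed RNG seed.
#' @param junkRate probability a controlled cell gets a novel string
#'   (destined to become a new term).
#' @return a \linkS4class{SubmissionMatrix} over the store's categories.
#' @export
generateSubmissionMatrix <- function(store, nRows = 5L, seed = 1L,
                                     junkRate = 0.1) {
  withSeed(seed, {
    cats <- store@categories
    df <- as.data.frame(
      stats::setNames(rep(list(character(nRows)), length(cats)),
                      names(cats)),
      check.names = FALSE, stringsAsFactors = FALSE)
    for (nm in names(cats)) {
      cls <- cats[[nm]]@valueClass
      for (ri in seq_len(nRows)) {
        if (nm == "sampleLabel") {
          df[ri, nm] <- sprintf("sample_%02d", ri)
        } else if (cls == "freetext") {
          df[ri, nm] <- if (stats::runif(1) < 0.5) ""
                        else paste("note", ri)
        } else if (cls == "numeric") {
          df[ri, nm] <- if (stats::runif(1) < 0.2) ""
                        else formatC(stats::runif(1, 0.1, 500),
                                     digits = 3, format = "fg")
        } else {
          v <- store@vocabularies[[nm]]
          if (!length(v@mainTerms)) { df[ri, nm] <- ""; next }
          mkValue <- function() {
            u <- stats::runif(1)
            term <- sample(v@mainTerms, 1L)
            if (u < junkRate) {
              paste("novel", randomWord(2L, 3L), randomWord(2L, 3L))
            } else if (u < junkRate + 0.25 && length(v@synonymMap)) {
              sample(names(v@synonymMap), 1L)
            } else if (u < junkRate + 0.45 && nchar(term) >= 4L) {
              generateTypos(term, 1L, edits = 1L,
                            seed = sample.int(1e6, 1L))
            } else if (u < junkRate + 0.65) {
              toupper(term)
            } else {
              term
            }
          }
          if (stats::runif(1) < 0.1) {
            df[ri, nm] <- ""
          } else if (stats::runif(1) < 0.15) {
            df[ri, nm] <- paste(mkValue(), mkValue(), sep = ";")
          } else {
            df[ri, nm] <- mkValue()
          }
        }
      }
    }
    submissionMatrix(cats[names(cats)], df)
  })
}

#' Build confirmations for everything a run leaves unresolved
#'
#' Runs the first two passes and converts every pending value into a
#' confirmation: accept the top-ranked candidate when one exists and
#' \code{policy = "accept_top"}, otherwise adopt the value as a new term.
#' One round is always enough, since the pending set enumerates every
#' unresolved value.
#'
#' @param x a \linkS4class{SubmissionMatrix}.
#' @param store a \linkS4class{VocabularyStore}.
#' @param models fitted models.
#' @param policy "new_term" adopts everything; "accept_top" prefers the top
#'   proposal where there is one.
#' @param acceptThreshold,proposeThreshold matcher settings.
#' @return a \linkS4class{ConfirmationSet} sufficient for
#'   \code{\link{standardize}} to complete.
#' @export
autoConfirmations <- function(x, store, models = fitModels(store),
                              policy = c("new_term", "accept_top"),
                              acceptThreshold = 0.80,
                              proposeThreshold = 0.20) {
  policy <- match.arg(policy)
  pend <- tryCatch({
    standardize(x, store, models,
                acceptThreshold = acceptThreshold,
                proposeThreshold = proposeThreshold)
    NULL
  }, metacurate_pending = function(cond) pendingValues(cond))
  conf <- confirmationSet()
  if (is.null(pend)) return(conf)
  for (i in seq_len(nrow(pend))) {
    cand <- pend$candidates[[i]]
    if (policy == "accept_top" && nrow(cand)) {
      conf <- confirmProposal(conf, pend$category[i], pend$original[i],
                              cand$term[1L])
    } else {
      conf <- confirmNewTerm(conf, pend$category[i], pend$original[i])
    }
  }
  conf
}

#' Write the full fixture set to a directory
#'
#' The command-line \code{fixtures} subcommand: the species-rule taxdump
#' fixture, the tree-number fixture, a generated orthogonal vocabulary
#' store, and the worked-example submission CSV.
#'
#' @param dir output directory.
#' @param seed RNG seed for the generated store.
#' @return \code{dir}, invisibly.
#' @export
writeFixtures <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  speciesRuleFixture(file.path(dir, "species-rules"))
  treeNumberFixture(file.path(dir, "tree-numbers"))
  store <- generateVocabularyStore(fixtureConfig(seed = seed))
  saveStore(store, file.path(dir, "generated-vocabularies"))
  wex <- workedExample()
  saveStore(wex$store, file.path(dir, "worked-example-vocabularies"))
  writeSubmission(wex$matrix, file.path(dir, "worked-example.csv"))
  invisible(dir)
}
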
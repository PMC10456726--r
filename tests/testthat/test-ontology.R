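writeTaxdump <- function(nodes, names) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  np <- file.path(dir, "nodes.dmp"); mp <- file.path(dir, "names.dmp")
  writeLines(nodes, np); writeLines(names, mp)
  list(nodes = np, names = mp)
}

test_that("taxdump reader builds the graph with synonyms from name classes", {
  f <- writeTaxdump(
    c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tgenus\t|",
      "3\t|\t2\t|\tspecies\t|"),
    c("1\t|\troot\t|\tscientific name\t|",
      "2\t|\tMus\t|\tscientific name\t|",
      "3\t|\tMus musculus\t|\tscientific name\t|",
      "3\t|\tmouse\t|\tcommon name\t|"))
  g <- readTaxdumpDialect(f$nodes, f$names)
  expect_identical(nrow(graphNodes(g)), 3L)
  expect_identical(graphSynonyms(g)[["3"]], "mouse")
  expect_identical(g@parents[["3"]], "2")
  expect_identical(g@parents[["1"]], character(0))  # self-parent = root
})

test_that("taxdump reader rejects cycles, dangling parents and dup names", {
  f <- writeTaxdump(
    c("1\t|\t2\t|\tgenus\t|", "2\t|\t1\t|\tspecies\t|"),
    c("1\t|\ta\t|\tscientific name\t|",
      "2\t|\tb\t|\tscientific name\t|"))
  expect_error(readTaxdumpDialect(f$nodes, f$names), "acyclic")
  f <- writeTaxdump(c("1\t|\t9\t|\tgenus\t|"),
                    c("1\t|\ta\t|\tscientific name\t|"))
  expect_error(readTaxdumpDialect(f$nodes, f$names), "dangling parent")
  f <- writeTaxdump(c("1\t|\t1\t|\tgenus\t|"),
                    c("1\t|\ta\t|\tscientific name\t|",
                      "1\t|\tb\t|\tscientific name\t|"))
  expect_error(readTaxdumpDialect(f$nodes, f$names),
               "duplicate scientific name")
})

test_that("tree-number reader infers parentage segment-wise", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\theadings\tsynonyms",
               "alpha\tA01\t",
               "beta\tA01.1\t",
               "gamma\tA011\t",
               "dual\tA01.2;C04.9\t",
               "cbranch\tC04\t"), p)
  g <- readTreeNumberDialect(p)
  expect_identical(g@parents[["beta"]], "alpha")
  # A01 is not a segment parent of A011
  expect_identical(g@parents[["gamma"]], character(0))
  expect_setequal(g@parents[["dual"]], c("alpha", "cbranch"))
})

test_that("tree-number reader handles empty files and bad headings", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), p)
  g <- readTreeNumberDialect(p)
  expect_identical(nrow(graphNodes(g)), 0L)
  writeLines(c("term\theadings\tsynonyms", "x\t.bad.\t"), p)
  expect_error(readTreeNumberDialect(p), "malformed tree number")
})

test_that("subtreeTerms has set semantics over roots and diamonds", {
  g <- ontologyGraph(
    data.frame(id = c("r", "a", "b", "d"),
               name = c("root", "left", "right", "diamond")),
    parents = list(r = character(0), a = "r", b = "r", d = c("a", "b")))
  expect_setequal(subtreeTerms(g, "r")$name,
                  c("root", "left", "right", "diamond"))
  # reachable from both included roots, counted once
  expect_identical(sum(subtreeTerms(g, c("a", "b"))$id == "d"), 1L)
  expect_error(subtreeTerms(g, "nope"), "unknown root")
})

test_that("subtreeTerms agrees with brute-force reachability on random DAGs", {
  for (seed in c(3, 17, 41)) {
    dag <- randomParentDag(120, seed)
    g <- ontologyGraph(data.frame(id = dag$ids, name = dag$ids),
                       parents = dag$parents)
    set.seed(seed + 1)
    roots <- sample(dag$ids, 4)
    expect_setequal(subtreeTerms(g, roots)$id,
                    reachableFrom(dag$parents, dag$ids, roots))
  }
})

test_that("exclusion rules drop what they say and compose conjunctively", {
  fix <- speciesRuleFixture(withr::local_tempdir())
  g <- readTaxdumpDialect(fix$nodesPath, fix$namesPath)
  all <- subtreeTerms(g, "1")$id
  # rank rule
  expect_false("6" %in% applyExclusions(all, g, list(dropRank("strain"))))
  # digit rule hits the influenza species
  expect_false("12" %in% applyExclusions(
    all, g, list(dropRankNameMatchingDigits("species"))))
  # the environmental-samples subtree goes as a whole (flag node + child)
  kept <- applyExclusions(all, g, list(
    dropDescendantsOfNameContaining("environmental sample")))
  expect_false(any(c("7", "8") %in% kept))
  # 'vector' species rule
  expect_false("13" %in% applyExclusions(
    all, g, list(dropRankNameContaining("species", "vector"))))
  # rules on absent ranks are vacuous
  expect_setequal(applyExclusions(all, g, list(dropRank("phylum"))), all)
})

test_that("rule application is invariant under permutation", {
  fix <- speciesRuleFixture(withr::local_tempdir())
  g <- readTaxdumpDialect(fix$nodesPath, fix$namesPath)
  all <- subtreeTerms(g, "1")$id
  base <- applyExclusions(all, g, fix$spec@exclusions)
  set.seed(5)
  for (i in 1:5) {
    perm <- sample(fix$spec@exclusions)
    expect_setequal(applyExclusions(all, g, perm), base)
  }
})

test_that("subtractReference is a normalized set difference", {
  ref <- c("Homo sapiens", "mus musculus")
  expect_setequal(subtractReference(c("balb/c", "HOMO  SAPIENS"), ref),
                  "balb/c")
  expect_setequal(subtractReference(c("a", "b"), c("c")), c("a", "b"))
  expect_length(subtractReference(c("homo sapiens"), ref), 0)
})

test_that("buildVocabulary yields the recorded species survivor set", {
  fix <- speciesRuleFixture(withr::local_tempdir())
  g <- readTaxdumpDialect(fix$nodesPath, fix$namesPath)
  v <- buildVocabulary(g, fix$spec, "species")
  expect_setequal(mainTerms(v), fix$expectedSurvivors)
  expect_identical(unname(synonymMap(v)["mouse"]), "mus musculus")
  expect_identical(nrow(validateStore(vocabularyStore(v))), 0L)
  # no exclusions keeps every name
  v2 <- buildVocabulary(g, extractionSpec("1"), "species")
  expect_length(mainTerms(v2), nrow(graphNodes(g)))
})

test_that("buildVocabulary dedupes names and drops colliding synonyms", {
  g <- ontologyGraph(
    data.frame(id = c("1", "2", "3"),
               name = c("root", "Shared Name", "shared  name")),
    synonyms = list(`3` = c("root", "other synonym")),
    parents = list(`1` = character(0), `2` = "1", `3` = "1"))
  expect_message(v <- buildVocabulary(g, extractionSpec("1"), "organ"),
                 "dropping synonym 'root'")
  expect_setequal(mainTerms(v), c("root", "shared name"))
  expect_identical(names(synonymMap(v)), "other synonym")
})

test_that("extraction specs round-trip through their JSON form", {
  fix <- speciesRuleFixture(withr::local_tempdir())
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    include_roots = list("1"),
    exclusions = list(
      list(type = "drop_rank", rank = "strain"),
      list(type = "drop_descendants_of_name_containing",
           substring = "environmental sample"),
      list(type = "drop_descendants_of_name_containing",
           substring = "unclassified"),
      list(type = "drop_rank_name_containing", rank = "no rank",
           substring = "/"),
      list(type = "drop_rank_name_matching_digits", rank = "species"),
      list(type = "drop_rank_name_containing", rank = "species",
           substring = "vector"))), p, auto_unbox = TRUE)
  spec <- readExtractionSpec(p)
  g <- readTaxdumpDialect(fix$nodesPath, fix$namesPath)
  expect_setequal(mainTerms(buildVocabulary(g, spec, "species")),
                  fix$expectedSurvivors)
})
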
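# shared fixtures and independent oracles for the suite

# a tiny hand-built store with the classic species synonyms; extra standard
# categories (e.g. "age") can be registered alongside
tinyStore <- function(extra = character()) {
  vocabs <- list(
    vocabulary("species",
               c("mus musculus", "arabidopsis thaliana"),
               c(mouse = "mus musculus", mice = "mus musculus",
                 "house mouse" = "mus musculus")),
    vocabulary("drugName", c("dexamethasone", "ibuprofen")))
  cats <- c(lapply(vocabs, vocabCategory),
            list(standardCategory("sampleLabel")),
            lapply(extra, standardCategory))
  vocabularyStore(vocabs, categories = cats)
}

# independent dynamic-programming Levenshtein distance (the oracle for the
# typo generator; deliberately not the same code path as anything in R/)
levDP <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  prev <- 0:length(y)
  for (i in seq_along(x)) {
    cur <- numeric(length(y) + 1L)
    cur[1L] <- i
    for (j in seq_along(y)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[length(y) + 1L]
}

# brute-force transitive reachability on a parent map (oracle for
# subtreeTerms): a node is in the subtree iff it is a seed or some parent
# chain reaches a seed
reachableFrom <- function(parents, ids, seeds) {
  inSet <- ids %in% seeds
  names(inSet) <- ids
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (id in ids) {
      if (!inSet[[id]] && any(unlist(parents[[id]]) %in%
                              ids[inSet[names(inSet)]])) {
        inSet[[id]] <- TRUE
        changed <- TRUE
      }
    }
  }
  ids[inSet]
}

# random DAG in the parent-map representation used by OntologyGraph
randomParentDag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)[-1L]) {
    k <- sample(0:min(2L, i - 1L), 1L)
    if (k > 0L) parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], k)
    else parents[[ids[i]]] <- character(0)
  }
  parents[[ids[1L]]] <- character(0)
  list(ids = ids, parents = parents)
}
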
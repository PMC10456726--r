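# metacurate

Controlled-vocabulary standardization of sample-metadata matrices for
metabolomics and proteomics submission pipelines.

## The problem

Meta-analysis across studies needs sample-level metadata that a program can
query. When every lab writes its own freetext — "mouse", "mice",
"M. musculus" — aggregating samples means natural-language guesswork. If
every submission is instead standardized against controlled vocabularies,
collecting all mouse samples reduces to a string-equality test:
`species == "mus musculus"`.

`metacurate` implements the machinery for that: orthogonal controlled
vocabularies built by subsetting ontology dumps, a character-trigram tf-idf
nearest-neighbor matcher that tolerates typos and unknown synonyms, and a
three-pass pipeline that converts a freetext submission matrix (rows =
samples, columns = metadata categories) into a standardized matrix with a
hard guarantee: after a successful run, every non-empty controlled cell is a
main term of the (possibly grown) vocabulary.

## The matcher

Every vocabulary surface (main terms and synonyms alike) is embedded in a
vector space whose dimensions are the union of the character trigrams of all
surfaces, sliding over the full string including spaces: `mus musculus`
contributes `mus`, `us␣`, `s␣m`, `␣mu`, `usc`, … (ten windows, `mus` twice).
A surface *s* gets the weight

    w(g, s) = tf(g, s) · idf(g),   idf(g) = ln((1 + D) / (1 + df(g))) + 1

per trigram *g* (raw count tf, smoothed inverse document frequency over the
*D* surfaces), L2-normalized. A query is coerced into this space (unknown
trigrams are dropped) and candidates are ranked by cosine similarity.

Standardization then runs in three passes:

1. **exact / synonym / nearest neighbor** — exact hits and synonym hits
   resolve at similarity 1.0; otherwise the top cosine candidate is applied
   automatically at or above an accept threshold (default 0.80), proposed
   for confirmation above a propose threshold (default 0.20), else left
   unmatched. Numeric categories (mass, age, dose, …) are validated as
   numbers, never curated; freetext categories pass through.
2. **substring rescue** — unresolved values that contain, or are contained
   in, a vocabulary surface become proposals (never auto-applied).
3. **new-term adoption** — everything still unresolved needs a user
   confirmation: accept a proposal, or adopt the value as a new main term.
   Adopted terms enter the vocabulary (orthogonality across categories is
   enforced — a main term identifies its category) and the models are
   refit, so the next submitter finds the term waiting.

## Worked example

The package ships a complete fixture modeled on an ozone-exposure lung
study: mice exposed to house dust mite allergen and then ozone, described
over the headers organ, mass, massUnit, species, sex, age, ageUnit, strain,
drugName, drugDoseMagnitude, drugDoseUnit, zeroTimeEvent, time, timeUnit.

```r
library(metacurate)
wex <- workedExample()

# without confirmations, the pipeline reports what it cannot settle:
pend <- tryCatch(standardize(wex$matrix, wex$store),
                 metacurate_pending = pendingValues)
pend[c("category", "original")]
#>        category          original
#> 1      drugName             ozone
#> 2  drugDoseUnit         hours/day
#> 3 zeroTimeEvent allergen exposure

# confirm the three as new terms and run to completion:
res <- standardize(wex$matrix, wex$store, confirmations = wex$confirmations)
matrixData(res$matrix)[1, c("species", "strain", "drugName", "drugDoseUnit")]
#>        species strain drugName drugDoseUnit
#> 1 mus musculus balb/c    ozone    hours/day

table(reportEntries(res$report)$pass)
#>       empty       exact    new_term passthrough     synonym
#>           6          11           8          18          17
```

"mouse", "Mouse", "mice" and "house mouse" all became `mus musculus` via
synonym hits; `BALB/c` normalized to the main term `balb/c`; the three
novel strings were adopted into their vocabularies, so re-running the same
submission resolves everything exactly. The standardized matrix can be
stored in a repository and queried by equality:

```r
repo <- addStudy(newRepository(res$store, res$models), res$matrix)
nrow(querySamples(repo, c(species = "mus musculus", sex = "female")))
#> [1] 2
```

A command-line front door (`inst/cli/metacurate`) wraps the same functions
as `standardize`, `build-vocab` and `fixtures` subcommands; exit code 2
signals a needs-confirmation stop and writes the pending proposals as JSON.

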
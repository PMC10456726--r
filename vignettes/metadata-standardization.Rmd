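---
title: "Standardizing sample metadata with trigram tf-idf vocabularies"
author: "metacurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing sample metadata with trigram tf-idf vocabularies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacurate)
```

## The model

`metacurate` treats sample-metadata curation as a controlled-vocabulary
problem. Each metadata category (species, organ, drugName, ...) owns a
vocabulary: a set of canonical *main terms* plus a many-to-one *synonym*
map onto them. Two invariants make the standardized output programmatically
useful:

* **Orthogonality.** Main-term sets of distinct categories are pairwise
  disjoint, so any standardized string identifies its category. Synonyms
  are exempt — natural-language surfaces like "mass" are unavoidable across
  categories, and only main terms ever appear in output.
* **Non-redundancy.** Within a category, main terms are distinct normalized
  strings and no synonym shadows a main term.

Matching is a character-trigram vector-space model. All surfaces — main
terms *and* synonyms, each as its own row mapped to its main term — are
decomposed into length-3 sliding windows over the full string, spaces
included, with multiplicity and no boundary padding. The component space is
the union of these trigrams; a surface's vector is raw trigram count times
a smoothed inverse document frequency,
$\mathrm{idf}(g) = \ln\!\frac{1+D}{1+\mathrm{df}(g)} + 1$
over the $D$ surfaces, L2-normalized. Queries are coerced into this fixed
space (novel trigrams are dropped; a query sharing no trigram becomes the
zero vector) and scored by cosine similarity, which for non-negative
weights lies in $[0, 1]$.

The assumption behind trigram matching is that realistic surface variation
— typos, pluralization, word-order noise, partial names — preserves most
trigrams. It does nothing for semantic variation ("murine" vs "mouse");
that is what the curated synonym sets are for, and why synonyms are
first-class rows rather than being folded into the main term's vector: a
synonym should be *retrievable* at high similarity and then *mapped*.

## The three passes

1. **Automatic.** Exact main/synonym hits resolve at similarity 1.0.
   Otherwise the nearest surface decides: cosine at or above
   `acceptThreshold` is applied automatically; at or above
   `proposeThreshold` it becomes a proposal for the user; below, the value
   is unmatched. Numeric categories (magnitudes: mass, age, dose, time)
   must parse as decimal or scientific-notation numbers and pass through
   uncurated; freetext categories (sampleLabel, inclusion, exclusion,
   comment) pass through verbatim; empty cells are recorded as empty.
2. **Substring.** Values still open are searched as substrings of surfaces
   and vice versa, ranked by length ratio. Substring hits are only ever
   proposals: containment is weaker evidence than trigram cosine, and this
   pass exists to rescue fragments ("musc") and abbreviations, which
   deserve a human glance.
3. **Adoption.** Every remaining value needs a confirmation — either an
   accepted proposal (recorded as `nn_confirmed` or `substring` by
   provenance) or a new term, which is added to the category's vocabulary
   (orthogonality enforced at insertion) with the models refit. Missing
   confirmations stop the run with a condition enumerating the pending
   values and their candidates; *nothing* is mutated on a failed run, so a
   rejected submission never pollutes the vocabularies.

The result carries a per-value curation report, and the pipeline's
guarantee — every non-empty controlled value of the output is a main term
of the updated store — is re-checked by the repository layer whenever a
study is ingested. A second standardization of an already-standardized
matrix is the identity, with every controlled value resolving exactly.

## Parameters that matter

| parameter | default | rationale |
|---|---|---|
| `n` (gram length) | 3 | the canonical trigram choice; shorter grams lose specificity, longer ones lose typo tolerance. Configurable but default-locked. |
| `acceptThreshold` | 0.80 | cosine above which a match is applied without confirmation. High enough that, on the fixtures, only near-duplicates (plural forms, single typos of long terms) auto-apply. |
| `proposeThreshold` | 0.20 | floor below which candidates are considered noise. One shared rare trigram between short strings typically scores below this. |
| `k` | 5 | candidates reported per query; zero-similarity rows are never candidates. |
| multi-value delimiter | `;` | values are curated independently and rejoined in input order. |

Both thresholds are honest knobs: the right operating point depends on the
deployment's tolerance for silent errors versus confirmation fatigue, and
the pipeline supports the full range from "everything needs confirmation"
(`acceptThreshold > 1`) to "always take the top hit"
(`acceptThreshold = 0`).

## Numerical and tie-break choices

* Similarities are ranked on their value **rounded to 12 decimals**, then
  by shorter surface, then lexicographically. Mathematically tied cosines
  computed in different summation orders differ in the last few ulps; the
  rounding makes the deterministic tie-break well defined and identical
  between the sparse-matrix path and the brute-force oracle. Reported
  similarities are unrounded.
* Surfaces and queries shorter than 3 characters contribute themselves as
  a single gram — otherwise one-letter units ("g") would be
  unrepresentable.
* The idf is smoothed (`+1` inside and outside the log) so no weight is
  ever zero and refitting after term adoption cannot divide by zero.
* String normalization is lowercase + whitespace collapse only.
  Punctuation is significant ("balb/c", "hours/day") and is never
  stripped; numeric validation rejects locale comma decimals to keep CSV
  semantics unambiguous across tools.
* Heading-prefix parentage in tree-number dumps is segment-wise: `A01`
  covers `A01.111` but not `A011`; a bare letter covers its whole heading
  class.
* Subtree exclusion rules are evaluated against the whole graph and their
  drop sets unioned, so rule application is conjunctive and order-free by
  construction.

## The brute-force oracle

`bruteForceNearest()` recomputes gram counts, document frequencies, idf
weights and per-pair cosines directly from the vocabularies with dense
per-surface arithmetic — no shared index, no shared matrix code. The test
suite and the acceptance script drive both paths over the same seeded
query mix (vocabulary surfaces, 1–2-edit typo variants, random strings)
and require identical top-1 terms and similarities within 1e-9. This is
the package's defense against the classic failure mode of indexed
similarity search: a fast path that silently disagrees with the
definition.

## What the synthetic data does and does not emulate

The fixture generator produces pronounceable multi-word terms with
category-specific prefixes (orthogonality by construction), synonym sets
at a configurable rate, typo corpora at verified exact edit distance
(checked against an independent dynamic-programming Levenshtein), ontology
dumps in both supported dialects — including an 18-node taxonomy in which
each of the six species exclusion rules (rank "strain", parent name
containing "environmental sample", parent name containing "unclassified",
"no rank" containing "/", species containing digits, species containing
"vector") removes at least one node, with the survivor set hand-derived —
and random freetext submission matrices mixing exact terms, synonyms,
typos, case mangling, novel strings, empties and delimited multi-values.

What it does not emulate: the scale of real ontologies (hundreds of
thousands of terms; term counts of real vocabulary builds are version
dependent and deliberately not reproduced), the skewed character
distributions of real biomedical nomenclature, semantic synonymy beyond
the curated maps, and multilingual input. Passing tests therefore show the
machinery is correct under its stated contracts, not that 0.80 is the
right accept threshold for production traffic of any particular
repository.

The worked example is the one richly realistic fixture: the ozone
lung-study matrix with its fifteen headers. Its category structure, the
"mouse"→"mus musculus" mapping and the three adopted terms ("allergen
exposure", "ozone", "hours/day") are anchored to the use case the design
follows; the numeric magnitudes in its cells are synthetic placeholders.
Representing the allergen exposure as the zero-time event (rather than as
a second drug) is one of several defensible encodings; the fixture fixes
one so the expected outputs are exact.

## Problem sizes

The suite and the acceptance script run at deliberately desk-friendly
sizes, chosen as the smallest that still exercise every contract: a
500-term vocabulary with ~30% synonyms and 1000 mixed queries for oracle
equivalence; 50 seeded random matrices (3 samples, 3 controlled
categories) for the guarantee/idempotence property; 100 persistence
round-trips; DAGs up to ~200 nodes for reachability checks. All randomness
flows from explicit seeds, and identical seeds give byte-identical
fixtures and results.

## Design decisions that were genuinely open

* **One model per category.** Matching a species cell against drug names
  is never useful, and per-category spaces keep idf statistics meaningful.
  The fitting function happily accepts several vocabularies at once for
  callers who want a shared space.
* **Auto-apply versus confirm-everything.** Whether a first-pass top hit
  should apply without confirmation is genuinely ambiguous in interactive
  use; the two thresholds subsume both policies, with exact hits always
  automatic.
* **Synonym collisions at build time drop the synonym**, never the main
  term: main terms are the identity anchors of the whole scheme.
* **Vocabulary versioning** is a per-category integer bumped on every
  mutation; fitted models record the versions they were fitted on and the
  pipeline and service refuse stale models rather than serving silently
  wrong similarities.
* **The service layer is an in-process request dispatcher** with JSON-able
  bodies (`handleRequest()`), plus a file-backed repository. It is the
  endpoint surface a web layer would mount; HTTP transport, deployment and
  authentication are out of scope here.
* **OBO/XML ontology sources** are expected to be pre-converted to the
  tree-number dialect; only the two text dialects are first-class, which
  keeps the parsing surface small while every exclusion rule stays
  exercisable.

## Known limitations

* The exclusion-rule set is closed by design; a genuinely novel filtering
  need requires a new rule type, not a user-supplied predicate.
* Substring rescue on very short queries (one or two characters) proposes
  liberally; such values should usually be units, which exact and synonym
  matching handle first.
* The orthogonality invariant forces globally unique main terms even where
  categories are semantically close (ageUnit versus timeUnit both wanting
  "week"); the deployment must partition such unit sets, exactly as the
  fixture store does.
* Cells are independent: the pipeline cannot express relationships like
  co-culture proportions between delimited species values, and a fixed
  tabular schema can never capture every study design — the freetext
  comment/inclusion/exclusion categories are the escape hatch.
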
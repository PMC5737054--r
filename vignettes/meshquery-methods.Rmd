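---
title: "Methods: MeSH query expansion, BM25 retrieval, and inferred evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MeSH query expansion, BM25 retrieval, and inferred evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshquery)
```

## The retrieval problem

Dataset metadata records are short, nested JSON documents whose
vocabulary rarely matches the queries of the researchers searching for
them. `meshquery` models one well-established answer — automatic query
expansion from a curated controlled vocabulary — as a complete, offline,
deterministic pipeline: flatten and index the records, expand queries
with MeSH-style synonyms, rank with BM25, and evaluate against graded
relevance judgments, including the inferred estimators used when only a
sample of the judging pool is graded.

## Corpus model

Records are stored as independent documents. Nested structure is
flattened to dot-separated paths; array indices are dropped and sibling
values merged under the parent path, which deliberately discards the
relationships between fields inside arrays of objects — all fields are
treated as unstructured text, concatenated (in sorted-path order, for
determinism) into a single searchable catch-all field. Per-field search
and boosting are out of scope. Parsed numbers are rendered with
`as.character()`, a deterministic textual form chosen because the JSON
parser does not preserve source bytes.

Unparseable inputs are counted and skipped, never aborting an import;
duplicate document ids abort, because silently overwriting records would
corrupt any subsequent evaluation.

Tokenization is UAX-29 word segmentation (via `stringi`), lowercased,
with punctuation-only segments dropped. There is no stemming and no
index-side stopword removal: stopwording is purely a query-side
operation, so document text remains fully recoverable from the index.

## Query model

Preprocessing lowercases the raw query, removes common lead-in words and
phrases with whole-word regular expressions, tokenizes, and removes
English stopwords. Both word lists are packaged, versioned fixtures
(`inst/extdata/`), not hard-coded truth — the exact phrase list is
configuration, and replacing it changes only the baseline query, nothing
downstream.

Each baseline token looks up at most `max_terms` synonyms from a local
TSV table whose file order is the canonical term order; an offline table
makes runs reproducible where a live vocabulary service would not be.
All fetched terms are concatenated into one string and re-tokenized with
the index tokenizer, so multiword headings like "Carcinoma, Basal Cell"
decompose into word tokens rather than phrases. The resulting bag is
deduplicated (first occurrence wins): repeated synonym words would
otherwise silently inflate the expansion clause's weight. Baseline
tokens reappearing as synonyms are *not* removed from the bag — the two
clauses are additive, and double-counting across clauses is exactly what
the clause weights control.

## Ranking

BM25 with `k1 = 1.2`, `b = 0.75` and the non-negative smoothed idf
`ln(1 + (N − df + 0.5)/(df + 0.5))` — the defaults of a stock version-5
Lucene-family engine, none of which this package retunes. The combined
query has "should" semantics: a document matching either clause is a
candidate, and

`score(d) = w_baseline · BM25(baseline, d) + w_mesh · BM25(expansion, d)`.

The ratio string `"1:5"` is read mesh:baseline (the expansion clause
counts one-fifth as much). One published table header reads the
orientation the other way; since the orientation is genuinely ambiguous
in the literature this package makes it explicit config — the parser is
documented as mesh:baseline, and both weights can be set directly to get
the opposite reading. Scaling both weights by any c > 0 provably leaves
the ranking unchanged (tested).

Ties are broken by ascending document id. A search engine's internal tie
order is nondeterministic; a stable rule is required for byte-identical
run files, which the tests assert. Scores are printed with six decimals
in TREC run files for the same reason.

## Evaluation

Grades are 0/1/2 (not / partially / fully relevant); unjudged documents
count as grade 0. Gains are linear in the grade with the `1/log2(i+1)`
discount — the treceval-family convention; exponential gains
(`2^g − 1`) are available behind a flag. AP and infAP binarize at grade
≥ 1 by default (partial counts as relevant), with a flag to require
grade 2. Reported per query and as unweighted arithmetic means: infAP,
infNDCG over the full submitted list, NDCG@10, and P@10 in both
variants.

**infNDCG.** Within each sampling stratum, the count of grade-g
documents is estimated as (sampled count)/rate, and the mean sampled
gain stands in for pooled-but-unsampled documents; documents outside the
pool contribute zero expected gain (a condition-on-pool convention). The
ideal DCG fills ranks with the estimated number of gain-2 documents,
then gain-1; a fractional estimated count contributes fractionally at
the next rank, and subsequent filling resumes at the rank after that.
The ideal fill is not truncated at the run length. A stratum with no
sampled documents contributes mean gain 0. The ratio is clamped to
[0, 1].

**infAP.** For each sampled relevant document at rank k, expected
precision above k is estimated from the pooled and sampled documents
above, with Lidstone smoothing `eps = 1e-5` (the literature default,
exposed in the API); stratified counts are weighted by reciprocal
sampling rates. When every rate is 1 and the whole pool is judged, the
sample is a census: no estimation is needed, no smoothing is applied,
and the implementation delegates to the exact AP — making the
full-information reduction exact rather than accurate to O(eps), which
is the governing contract for both inferred metrics (tested to 1e-9).
The exact estimator variant inside any particular challenge's scoring
script is not published, so absolute agreement with officially reported
scores is not claimed; the reductions and the enumeration test define
correctness here.

**Sampling.** `sampleQrels()` pools the top-depth documents across runs;
a document's stratum comes from its best rank in any run. Each
(query, stratum) is sampled without replacement at its rate with a
floor-plus-randomized-remainder rule, so sample sizes are deterministic
given the seed.

## Synthetic collections

The generator builds collections around latent concepts: each concept
has one query-side token and several document-side synonym forms, all
registered in the emitted synonym table. With probability ρ (the
mismatch rate) a concept is *masked* — documents mention it only through
synonyms — so ρ is a dial on exactly the failure mode expansion
addresses. Grades come from exact concept coverage against thresholds
θ1/θ2, so the ground truth is exact and recountable rather than
probabilistic. Query concepts are drawn from a randomly chosen
document's concepts, guaranteeing at least one fully relevant document
per query.

Defaults, chosen once as a plausible desk-scale analogue of a dataset
retrieval collection: 500 documents, 30 concepts, 3 synonyms per
concept, 3 concepts per document, 2 per query, 10 queries, ρ = 0.5,
30 Zipf-distributed noise tokens per document (exponent 1.1 — uniform
noise would make idf uninformative), θ1 = 0.5 and θ2 = 1.0 (cover half
the query's concepts for partial relevance, all of them for full), and
two sampling strata: depth 15 at rate 1.0, depth 100 at rate 0.3,
mirroring the judge-the-top-exhaustively-then-sample economy of shared
tasks.

What the generator does *not* emulate: real metadata schema diversity
and field sparsity, natural-language descriptions (documents are bags of
surface forms plus noise), ambiguous or misleading synonyms, and
correlated query difficulty. Passing the expansion-benefit tests
therefore shows the machinery recovers planted mismatch; it does not
predict effect sizes on any real corpus, where synonym quality is the
dominant unknown.

## Problem sizes and numerical choices

The test suite exercises: oracle equivalence on 200 randomized instances
(≤ 30 documents/query) at 1e-9; full-sampling reductions on 100
instances; the infAP enumeration over all 70 four-of-eight samples;
exhaustive-scoring equality on corpora up to 200 documents; and an
expansion study of 50 replicates per ρ ∈ {0, 0.4, 0.8} at 500 documents
and 10 queries each, asserting a non-decreasing mean advantage in ρ and
an expanded-beats-baseline rate of at least 90% at ρ = 0.8. The
acceptance script reports a 20-replicate version of the same study.
These sizes make every oracle exactly recomputable while keeping the
whole suite comfortably fast on one CPU.

Degenerate inputs are defined, not special-cased away: empty queries
return empty rankings with a warning and score zero when judged; 0/0
NDCG is 0; an empty synonym table simply disables expansion; `K = 0`
reproduces the baseline system exactly (tested as an identity on
rankings, not scores).

## Known limitations

- Single catch-all field: no per-field weighting, phrase queries, or
  structured filtering.
- Expansion adds every fetched synonym; no disambiguation, filtering or
  statistical re-weighting of terms — the light clause weight is the
  only guard against poorly matched synonyms.
- The synonym table is static; coverage is whatever the table provides.
- In-memory index; collections of hundreds of thousands of records are
  out of desk scope.
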
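---
title: "Multi-level refinement of text-mined knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level refinement of text-mined knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlrkg)
```

## The problem and the model

Open information extraction over medical prose is noisy by construction.
A dependency parse of one sentence yields at most a handful of candidate
subject–verb–object triplets, but many slots come out empty (imperative
fragments, nominal sentences), many candidates are off-topic for the KG
being built, and guideline documents restate the same fact dozens of
times. `mlrkg` treats KG construction as a refinement cascade over an
ordered triplet table:

1. **extraction** — one candidate per verb token per sentence;
2. **keyword filter** — keep rows whose subject or object bears a
   domain keyword;
3. **completeness filter** — keep rows with all three slots non-empty;
4. **duplicate elimination** — keep the first occurrence of each
   normalised (source, edge, target) key;
5. **validation** — apply reviewer approve/reject annotations.

Each stage is a pure, order-preserving function of the table, so the
stage row counts are monotone non-increasing, and each stage is
idempotent where that makes sense (completeness, deduplication). The
surviving table defines a directed **multigraph**: nodes are normalised
entity labels, one edge per row, parallel edges allowed. The multigraph
choice is deliberate — repeated facts must survive until the explicit
deduplication stage so that the stage counts mean what they say, and so
that pre-deduplication frequencies remain available to the
query-triplet predictor.

## Extraction conventions

For each verb token V in a tagged sentence:

* the **subject** is the entity phrase of the first token with
  dependency `subject`/`passive-subject` headed by V;
* the **object** is the phrase of the first `direct-object`/`attribute`
  token headed by V, or else the first `prepositional-object` reachable
  through a single adposition headed by V, in which case the adposition
  surface is suffixed to the relation (yielding relations such as
  "binds to");
* an **entity phrase** is a head token plus every `compound`/`modifier`
  token whose head chain reaches it without crossing a verb, joined in
  sentence order ("cell" + "eosinophils" → "cell eosinophils").

One candidate is emitted per verb (no cross-product over conjuncts), and
a candidate is emitted even when a slot is empty: incomplete candidates
are data, counted and then removed by the completeness stage. Relations
keep the verb *surface* form by default ("included" ≠ "include" — they
are tallied separately by `top_relations()`); a lemma mode exists for
users who want the collapse. Modal-only and copular predicates are
allowed as relations, which is what lets a query-triplet convention like
("Asthma", "Am", "Asthma") align with extracted facts.

These conventions are choices, not consequences of the tagging model:
how verbs acquire their prepositions and which modifiers join an entity
phrase are under-determined by the data, so the package fixes the rules
above and exposes the alternatives (lemma mode, at-least joint matching,
the other DCG discount) as flags rather than silently picking per call.

## The tagger is a contract

Everything downstream consumes sentences of tagged tokens with a closed
coarse label set (six part-of-speech classes, ten dependency classes,
exactly one root per sentence). Any backend that produces that shape
qualifies; backend-specific label inventories are expected to be mapped
into the closed set by the caller's wrapper. The packaged
`fixture_tagger()` is a deterministic rule-based implementation (split on
`.!?` + whitespace; lexicon-driven verb/adposition recognition;
last-pre-verb-token subject, last-post-verb-token object, intervening
tokens as compounds). It exists so that tests and examples never download
a model, and so that extraction behaviour is pinned: absolute triplet
counts from any real corpus depend on the tagger version used, which is
exactly why no absolute count from a full document is treated as a
reproducible quantity anywhere in the package.

## Normalisation and identity

One normalisation rule is used for deduplication keys, graph node
identity, degree computation and prediction/truth alignment: lower-case,
collapse internal whitespace, strip leading/trailing punctuation. It is
the minimal rule that makes "Severe  Asthma." and "severe asthma"
the same node while keeping genuinely different phrases apart; no
stemming, no synonym folding — those belong to the (out-of-scope)
entity-linking layer. Original casing is retained for display on the
first-seen surface.

## Joint analysis

Over a deduplicated table, each entity gets a subject count *a* and an
object count *b* (each row contributes exactly one subject and one
object occurrence, so both counts sum to the row count — an invariant
the tests assert). key(*a*, *b*) selection is **exact-count** by default:
the constraint "four subject entities and three object entities" reads
literally as *a* = 4, *b* = 3. An at-least mode is available since the
looser reading is also defensible; exact mode is always a subset of it.
At level *n* the constraints with max(*a*, *b*) = *n* are enumerated in
subject-major order — (n,0)…(n,n), then (0,n)…(n−1,n) — which is 2n + 1
keys. Overlap colouring saturates upward: 2 participations map to the
orange class, 3 map to purple, and more than 3 stay purple (the severity
scale has nowhere further to go).

## Distillation

A query keyword pulls the edge-induced ego subgraph: at depth 1, every
edge in either direction incident to a matching node; at depth *d*, edges
touching any node captured earlier. Matching defaults to substring on
normalised labels because a query like "asthma" should retrieve "severe
asthma" facts; exact mode exists. Depth defaults to 1 — distilled answer
graphs are meant to be readable, and every extra hop roughly multiplies
the answer by the mean degree.

## Evaluation conventions

The query predictor ranks unordered entity pairs by co-occurrence
frequency (ties lexicographic, orientation from first observation) and
attaches a fixed relation. Against a deduplicated ground truth of size
*T* with hits at ranks *r₁…r_h*:

* recall = h/T, precision = h/k, F1 their harmonic mean;
* MRR = (Σ 1/rᵢ)/**T** and MAP = (Σ relᵢ/rᵢ)/**T** — normalised by
  ground-truth size. The standard convention divides by the number of
  queries; both are implemented (`mrr_standard()`), the ground-truth
  variant is the default because it is the convention the rest of this
  pipeline's reporting uses;
* DCG discounts rank 1 by nothing and rank i ≥ 2 by log2(i); IDCG is
  the DCG of the descending-sorted relevance list; nDCG their ratio.
  The discount follows from the worked identities 1 + 1/log2(3) and
  1 + 1/log2(2) = 2; the common log2(i + 1) discount is a flag.

Reported values are rounded half-up to four decimals; internal values
are kept at full precision and the package's own tests compare at
absolute tolerance 5 × 10⁻⁵. For graded MAP the built-in scenario
assigns grade 1 to the rank-1 hit and grade 2 to the rank-3 hit —
following the worked arithmetic convention rather than the opposite
prose gloss that sometimes accompanies such examples, since only the
arithmetic is checkable.

## The synthetic generator

`generate_fixture()` emits sentences written in the fixture tagger's own
grammar, so extraction must recover the planted table *exactly* — set
equality against the manifest is the extraction oracle. A configuration
plants: the incomplete fraction (default 0.15 — a minority but
non-negligible share, as typical of parses of guideline prose), the
duplicate fraction (default 0.1), the keyword-bearing fraction (default
0.4 with keyword "asthma"), exact entity-degree profiles (single-use
filler entities keep planted degrees uncontaminated), and exact pair
co-occurrence frequencies. Vocabulary is data (a JSON lexicon of
drug-like, symptom-like, comorbidity-like tokens and modifiers), not
code. Generation runs on a private RNG stream: the same seed gives
bit-identical corpora and the caller's RNG state is untouched.

What the generator does *not* emulate: real parser errors (wrong
attachments, mis-tagged verbs), coreference, negation, cross-sentence
relations, or realistic sentence length distributions. Passing the
fixture oracles therefore demonstrates that the pipeline's logic is
correct under its stated contracts, not that any particular tagger
achieves any particular accuracy on real documents.

The built-in `paper_scenario()` pins the evaluation conventions to a
worked end-to-end case: a deterministic 202-key ground truth, a query
log whose pair frequencies (10 down to 1) force the predicted ranking,
hits at ranks 1 and 3, and the six headline values
(0.0099 / 0.2 / 0.0066 / 0.0083 / 2 / 0.8155) that the acceptance script
recomputes at run time. Test problem sizes (500-sentence corpora for the
extraction oracle, 20 seeds for the distillation oracle) were chosen so
the whole suite runs in well under a minute while still exercising every
planted feature many times over.

## Degenerate inputs and numerical edges

Empty documents segment to zero sentences; verbless sentences yield zero
candidates; empty tables flow through every stage and produce empty
graphs, empty degree lists and header-only CSV files. All-zero relevance
gives (0, 0, 0) for DCG/IDCG/nDCG rather than 0/0. Metrics with zero
denominators return 0 by definition (recall with an empty truth set, F1
with two zeros). Conflicting approve/reject verdicts on one key are an
error, not a silent precedence rule. CSV interchange is RFC-4180 with
the `Source,Edge,Target` header, which round-trips commas and quotes in
entity phrases bit-exactly.

## Known limitations

* Extraction quality is bounded by the tagger; the fixture tagger's
  grammar is intentionally simple (one predicate per sentence, no
  conjunct expansion, no passive reordering).
* The keyword stage needs a user-supplied keyword list; no list is
  bundled, so absolute survivor counts on real corpora are not
  comparable across users.
* Normalisation does not link entities across surface variants
  ("ICS" vs "inhaled corticosteroids" are different nodes).
* The interactive HTML export favours self-containment over polish: a
  small embedded canvas renderer (force layout, wheel zoom, drag pan),
  not a full graph-exploration widget.
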
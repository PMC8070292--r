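---
title: "Mining knowledge networks from plant-science literature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining knowledge networks from plant-science literature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litkn)
```

## The problem and the model

Experimental evidence linking genes to phenotypes accumulates in free text
long before it reaches curated databases. `litkn` implements a deliberately
simple, fully transparent pipeline for surfacing such links from a dated
corpus: dictionary-based named entity recognition over a closed three-class
type system (gene/protein, metabolite, trait), within-sentence co-occurrence
as the relation signal, normalization of surface forms onto preferred
labels, an undirected co-occurrence network weighted by document frequency,
and a cumulative time-sliced shortest-path analysis around a designated
trait node set.

Two modeling commitments shape everything downstream:

* **Genes and proteins are one class.** The literature uses the two
  interchangeably; separating them costs precision and buys little for
  genotype–phenotype mining.
* **Relations live within a sentence.** Co-occurrence of two normalized
  entities in one sentence is taken as evidence of association. Most
  relations carry the generic `RELATED_TO` label; trigger keywords between
  the two mentions upgrade a pair to `ENCODES` or `PART_OF`. The relation
  registry is fixed at seven types, of which four are configurable
  placeholders that never fire without explicit triggers. Association
  polarity (positive/negative) is out of scope.

The interesting signal is *indirect* proximity: a gene two hops from the
trait (gene–metabolite–trait) is a candidate whose direct statement may
simply not have been written yet. The time analysis makes that precise.

## Dictionary matching

Tokenization treats runs of alphanumerics plus internal hyphens and
apostrophes as single tokens, because metabolite names are hyphen- and
digit-rich (`lutein-5,6-epoxide`); consequently `carotene` does not match
inside `beta-carotene-like`. Matching is case-insensitive at token
boundaries; among overlapping candidates the leftmost wins and, at equal
start, the longest (`zeaxanthin epoxidase` beats `zeaxanthin`). This is the
standard deterministic convention for dictionary annotators, and it makes
the mention set a pure function of sentence and lexicon.

Mentions that never take part in a relation are retained in the annotation
output but excluded from networks: a knowledge network contains no isolated
nodes by construction.

Abbreviation coreference across sentences (a gene introduced long-form, then
referred to by its abbreviation elsewhere) is *not* attempted; dictionaries
must list the forms they want found. Colliding abbreviations across domains
are a known failure mode of every annotator in this space and are out of
scope here.

## Normalization

Six rules run in a fixed order, then a synonym-table lookup:

1. Greek transliteration (`β` → `beta`, both cases) and token-wise
   American-spelling conversion (`colour` → `color`);
2. removal of apostrophes (including typographic variants) and `#` marks;
3. uppercase conversion;
4. species-prefix stripping (default prefixes `St`, `Le`, `Sl`, `Ca`, `At`,
   `Nt`);
5. gene-family suffix-digit stripping (`BCH1` → `BCH`);
6. EC-number expansion to enzyme names.

Only the position of the case/spelling conversion is externally fixed
("first"); the remaining order is this package's choice: character-level
cleanup precedes the dictionary-dependent rules so that prefix/suffix/EC
lookups see canonical text, which maximizes their hit rate. The order is
configurable (`rule_order`) for sensitivity checks.

Rules 4 and 5 are guarded: they fire only when the stripped remainder
resolves in the synonym table or a caller-supplied label pool. This prevents
damage of the `Or` → `O` kind — `Or` (a real gene) starts with a species
code but `"O"` resolves nowhere, and `CAROTENOID` keeps its leading `Ca`.
When prefix and suffix rules both apply, they apply in rule order, each
requiring resolvability of its own output. Unresolvable labels pass through
as their rule-processed uppercase form rather than erroring: an unknown
entity is still a usable node label.

Normalization is idempotent (property-tested), and allelic or isomeric
variants (`recessive ZEP`) collapse onto their main label *as synonym data*,
not as code.

## Networks and weights

Edges are unordered label pairs, deduplicated at the pair level; multiple
relation types between a pair collapse onto one edge carrying the type set.
The edge weight is the number of *distinct documents* contributing the pair
(mention-count weighting exists behind a flag, default off, for
exploration). Single-document edges are classed GREY, repeated ones BLACK —
the visual cue separating potentially novel from established associations.
A label that appears with two entity types after normalization is a hard
error rather than a silent merge: it invariably indicates a lexicon or
synonym defect, and silently merging would corrupt every downstream count.

Path lengths are unweighted hop counts; document frequency does not enter
distances. Distances in the published-style tables are small integers, and
hop counts are what the "n-th order neighbor" vocabulary refers to.

## The time analysis

Cumulative corpora (`subset_by_year`) guarantee two invariants that the
tests assert on every generated series: yearly networks nest (year *y* is a
subgraph of year *y*+1), and each tracked node's distance row is
non-increasing once numeric. The master table records, per tracked node and
year, the minimum shortest-path distance to *any* flesh node; `x` covers
both "node not yet present" and "present but disconnected" — the published
table shape does not distinguish them, and neither does ours (a verbose
caller can distinguish via the per-flesh-node `year_diff` report).

Tracked nodes default to the *eventual direct neighbors* of the flesh set:
the analysis works backwards from the most complete network, because that is
the vantage point from which "when did this candidate first get close?" is
well-posed. Tracked labels that are themselves flesh labels are dropped with
a warning (their distance would be trivially 0/1).

The transition detector reports, per node, the first year at distance ≤ *k*
for each requested threshold and the first direct-neighbor year (*k* = 1).
Lead time against an external anchor (say, the publication year of
experimental confirmation) is a helper whose anchor the caller supplies: the
package deliberately does not infer "years ahead of the literature" from the
table itself, since the choice of anchor is a scientific judgment, not a
graph property.

## The synthetic-data generator

The generator emulates the structure this pipeline assumes in its inputs:
yearly batches of short documents in which planted entity pairs co-occur
within template sentences, on a known emergence schedule. Its defaults are
the emulated study conditions — years 2000–2016, a few documents per year,
two distractor sentences per document, no off-schedule noise — and they are
not tuned per test.

Design points:

* **Distractors carry at most one entity**, so the planted graph is exactly
  the realized graph and the expected distance table is computable by an
  independent breadth-first-search oracle (`expected_distances`) that never
  touches the annotation or igraph code paths. End-to-end recovery of the
  planted table on noise-free corpora is the package's strongest test.
* **Surface variants are normalization stressors**: species prefixes
  (`StZEP`, `StAN1`), family digits (`BCH1`, `PSY1`), abbreviations
  (`NCED2`, `ABA`), Greek letters (`β-carotene`) and British spellings
  (`flesh colour`), so the normalize stage is exercised on every run, not
  only in unit tests.
* **Noise mode** adds off-schedule random relation sentences per document
  with probability `noise_rate`. Extra edges can only shorten shortest
  paths, so recovered transition years are never later than planted ones —
  asserted as a property test.
* One seed drives all sampling; identical seed and configuration give
  byte-identical corpora.

What passing these tests does *not* show: real abstracts are linguistically
richer (coordination, anaphora, hedging), real dictionaries are incomplete,
and real corpora contain entity mentions the lexicon misses entirely.
Synthetic perfection demonstrates the pipeline's internal consistency, not
its recall on wild text.

## Evaluation

Span-level scoring is micro-averaged: counts are pooled over documents, then
precision, recall and F1 (harmonic mean) are computed as percentages. The
default matching policy is `EXACT` (document, sentence, span and type all
equal); `OVERLAP` (intersecting spans, equal types) exists for robustness
studies, since annotation guidelines differ on boundaries. Matching is
greedy left-to-right with each gold annotation consumed at most once, which
makes the counts well-defined when predictions overlap. Scoring is at the
mention level, not the unique-entity level: each occurrence counts.

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open throughout; sentence indices
  0-based. Sentence spans tile the document (asserted by tests), so
  `substr(text, start + 1, end)` always recovers a sentence.
* Centroid ties break to the lexicographically smallest label; edge
  endpoints are stored sorted, and all exports are row-sorted, so repeated
  runs are byte-identical.
* Empty inputs flow through: an empty corpus yields empty annotation sets,
  an empty triple set yields an empty network, and an empty schedule yields
  an empty distance table.
* External master tables are validated strictly per cell (positive integer
  or `x`) but only *warned* about when rows violate monotonicity — a
  transcribed table is external evidence, not something the parser should
  reject outright.

## Problem sizes in the test suite

The suite runs entirely on generated data: random graphs up to 50 nodes for
the BFS cross-checks, 100 random planted schedules (2–7 events over 3–6
years, 2 documents per year) for end-to-end recovery, and a handful of
deeper bundles for determinism, noise and evaluation properties. These sizes
were chosen as the smallest at which the properties are non-trivial; the
whole suite completes in well under a minute on one core.

## Known limitations

* Dictionary NER finds only what the lexicon lists; there is no model-based
  generalization to unseen surface forms.
* All-pairs within-sentence co-occurrence over-generates relations in long
  enumerative sentences; document-frequency weighting mitigates but does not
  remove this.
* Cross-sentence relations and abbreviation coreference are not captured.
* Edge weights ignore how *strongly* a sentence asserts a relation;
  negated or speculative statements count the same as positive ones.
* Shortest-path proximity is sensitive to hub nodes (a promiscuous
  metabolite shortens many paths); interpreting a transition still requires
  a domain expert.
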
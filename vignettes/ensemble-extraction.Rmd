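---
title: "Ensemble clinical concept extraction: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble clinical concept extraction: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinconex)
```

## The pipeline and its assumptions

`clinconex` extracts standardized clinical concepts from free text by
combining several independent named-entity extractors. The stage order is
fixed and matters:

1. **Extraction.** Every backend in the roster returns surface mentions
   for the document. Backends are black boxes behind one contract
   (`extract_terms()`); a backend failure degrades the ensemble (that
   extractor is skipped with a warning) rather than aborting the run, and
   the run fails only if every backend fails.
2. **Negation.** NegEx-style trigger matching flags mentions inside
   negated regions; the κ switch decides whether flagged mentions are
   dropped.
3. **Normalization.** Each surviving mention is looked up in a concept
   lexicon that returns up to 10 ranked code matches, most similar first.
   The top-ranked code is the mention's identity for everything
   downstream.
4. **Per-extractor deduplication.** Within one extractor's output,
   mentions sharing a top code (or, for unmatched mentions, a normalized
   surface) collapse to their earliest occurrence, so repetition within a
   document does not multiply evidence.
5. **Integration.** Mentions from all extractors are pooled, merged into
   entities by code-list similarity (threshold γ), and accepted by
   cumulative extractor weight (threshold θ).

The central assumption is that *agreement between independent extractors
is evidence*: a concept found by many (or by highly reliable) backends is
probably real, while singleton findings from weak backends are probably
noise. A second assumption is that two mentions denote the same concept
exactly when their ranked code lists overlap — the code system, not string
similarity, carries identity.

## The double weight system

**Term similarity.** For normalized terms $a$ and $b$ with ranked code
lists (length ≤ 10),

$$ w(a,b) = \frac{\alpha}{4} + \frac{3\beta}{4}, $$

where $\alpha$ is the number of shared codes divided by 10 and $\beta$ the
number of codes shared between the two top-3 lists divided by 3. The
denominators are constants even when a list is shorter — a term with three
known codes can never look more similar than one with ten, which is the
conservative reading. $\beta$ dominates (weight 3/4) because agreement
among the most similar candidates is stronger evidence than agreement in
the tail. Terms merge when $w > \gamma$, strictly: a pair exactly at the
threshold does not merge. Codes compare as (system, code) pairs; a CUI
and an identically numbered ICD-10 code are different codes.

When the two top-3 lists differ, $\beta$ is computed as the intersection
of both top-3 *sets* over 3. This is a genuine design choice — one could
instead ask how many of one term's top-3 appear anywhere in the other's
list — and the symmetric-set reading was chosen because it keeps $w$
symmetric, which the merging step relies on.

**Merging is transitive closure.** Pairwise similarity alone does not
define a partition (A≈B and B≈C do not force A≈C), so entities are the
connected components of the similarity graph, computed by union–find and
verified in the tests against a brute-force closure oracle on random
instances. Transitive closure makes the partition — and, with the
deterministic entity ordering by representative surface — the whole result
invariant to extractor order and term order, which a greedy first-match
clustering would not be. The cost is that long similarity chains can
bridge dissimilar terms; with γ at its default and top-3-dominated
weights, chains beyond length 3 are rare in practice.

**Extractor reliability.** Each extractor's F1 on a held-out annotated
subset, sum-normalized over the roster
($\omega_i = F1_i / \sum_j F1_j$, `estimate_extractor_weights()`), gives
its vote weight. An entity's cumulative weight sums ω over the *distinct*
contributing extractors — an extractor that mentions a concept five times
still votes once — and the entity is accepted iff the sum strictly
exceeds θ. All ties at thresholds therefore resolve toward rejection
(fewer merges, fewer acceptances), which keeps the monotonicity
properties clean: raising γ never decreases the entity count, raising θ
never grows the accepted set, and switching κ on never raises recall.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| κ (`kappa`) | `FALSE` | negation filter on/off. Off by default: trigger-word negation detection has no access to sentence semantics, and on gold standards whose negated mentions are simply not annotated it mostly trades recall for little precision. |
| γ (`gamma`) | 0.1 | similarity threshold in [0, 1]. 0.1 is deliberately permissive: any shared top-3 code (β ≥ 1/3 ⇒ w ≥ 0.25) merges, and even 2 shared tail codes (α = 0.2 ⇒ w = 0.05) do not. |
| θ (`theta`) | 0.35 | acceptance threshold in [0, 1]. With six uniform extractors, 0.35 demands support from at least three (2/6 = 0.333 is rejected); with F1-estimated weights it demands either one very reliable backend or agreement between two. |
| ω (`omega`) | uniform | per-extractor weights; `pipeline_config()` fills in 1/n when none are given, `estimate_extractor_weights()` produces F1-normalized ones summing to 1. |
| NegEx window | 5 tokens | conventional scope bound; a trigger negates up to 5 tokens toward the end (pre-triggers) or the start (post-triggers) of its sentence, stopping at terminators ("but", "however"). |

`run_tune()` evaluates the full Cartesian grid over (κ, γ, θ) and reports
the argmax-F1 cell, breaking ties toward smaller θ, then smaller γ, then
κ off — i.e. toward the least aggressive configuration achieving the
best score.

## Evaluation

Counting is entity-level per document: greedy one-to-one matching of
accepted entities against gold annotations, code matches claimed before
surface matches so that a coded match is never stolen by a string
coincidence, each gold item matched at most once (one prediction cannot
satisfy two gold items, and vice versa). A matched *present* annotation
is a TP, a matched *absent* annotation (classification-style gold marks
concepts annotated as not in the document) is an FP, an unmatched present
annotation an FN. Entities matching nothing are FPs under exhaustive gold
and ignored under label-style gold, whose fixed label set does not cover
them. All 0/0 ratios are defined as 0, so empty documents and empty
predictions are well-behaved.

Documents are aggregated by micro-averaging (sum TP/FP/FN, then compute
metrics); `run_evaluate()` also reports the macro average. Micro is the
default because per-document metrics are unstable on documents with one
or two gold entities, and because it keeps the aggregate well-defined
when some documents have no gold at all.

## The synthetic-data generator

`simulation_spec()` + `generate_lexicon()` / `generate_corpus()` /
`simulate_extractor_outputs()` produce a complete offline study:
a lexicon of clinical stub surfaces plus pronounceable pseudo-terms (each
with 3–10 ranked CUI-style codes, every fifth pseudo-term paired with a
near-synonym sharing its top-2 codes so cross-surface merging is
exercised), template-prose documents with a controlled number of embedded
gold entities, a `negation_rate` fraction of them wrapped in negation
templates ("No X was found.", "Patient denies X.") and annotated absent,
and per-extractor outputs emitting each gold mention with a profile
sensitivity plus Poisson-rate spurious lexicon terms. Every generator is
a pure function of the spec's integer seed.

The default profiles — three extractors with sensitivities 0.9/0.8/0.7,
0.5 spurious mentions per document each, both categories supported — are
the conditions under which the package's ensemble-benefit property is
demonstrated: at the default configuration the weighted ensemble's F1
exceeds the worst single extractor's, and the estimated ω order the
extractors exactly as their measured solo F1s do. The acceptance script
runs this study at 50 documents; the test suite uses 5–50 documents per
case, sizes at which every property it asserts is already stable.

What the generator does **not** emulate, and what passing tests therefore
do not show: real discharge-letter language (abbreviations, typos,
section headers, de-identification artifacts), ambiguous surfaces needing
word-sense disambiguation, extractors whose errors are *correlated*
(real backends trained on similar data fail together, which weakens the
agreement-as-evidence assumption), and affirmative mentions sitting
inside negation scopes. That last point has a visible consequence: in
generated corpora only absent-gold entities are negated, so switching κ
on removes false positives but leaves recall exactly unchanged, whereas
on real text NegEx's blindness to semantics costs true mentions too (the
recall inequality the tests assert is ≤, and on synthetic data it is
typically equality).

## Numerical and degenerate-input choices

* Both thresholds are strict (`>`); weights exactly at γ or θ do not
  merge / are rejected.
* A term with an empty match list has similarity 0 to everything and is
  keyed by its normalized surface for deduplication and evaluation; an
  unknown surface is not an error.
* Spans are 0-based half-open character offsets; span-less terms (e.g.
  backends that return no offsets) are located by first surface
  occurrence for negation flagging and fall to the end of every ordering.
* Representative selection in a merged entity: most matches, then
  earliest span, then lexicographic surface — i.e. the best-normalized,
  earliest mention labels the cluster.
* Surface normalization is lowercase + punctuation stripping + whitespace
  collapsing, with a naive trailing-"s" singular fallback on lookup miss
  ("hematomas" hits "hematoma"); no stemming or lemmatization.
* Results serialize to JSONL with 17 significant digits, so a write/read
  cycle reproduces every double bit-exactly.
* Corpus readers sort by `doc_id` (radix order) and all entity orderings
  are explicit, so repeated runs are byte-identical.

## Known limitations

* NegEx here is the trigger-and-window core with a modest shipped trigger
  lexicon (editable TSV); it has no understanding of semantics, scope
  ambiguity, or hypotheticals, and more advanced negation models are out
  of scope.
* No word-sense disambiguation and no cross-system code translation; one
  code system is primary per lexicon.
* The REST adapters are a contract plus request/response mapping,
  exercised only against recorded or mock payloads; live-service
  behavior (schemas, rate limits, billing) is untested by design.
* Weight estimation assumes single-extractor F1s are measurable on some
  annotated subset; with no annotations, uniform weights are the
  fallback.
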
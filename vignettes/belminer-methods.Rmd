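---
title: "Methods: coreference-aware BEL statement extraction and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coreference-aware BEL statement extraction and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belminer)
```

## The problem

Causal biological knowledge — "protein X increases the degradation of
protein Y" — is published as prose. The Biological Expression Language
(BEL) encodes such knowledge as subject–relationship–object triples over
namespaced entity terms, e.g.

```
p(MGI:Mdm2) increases deg(p(MGI:Trp53))
```

Automatic BEL extraction pipelines typically chain an event extractor
(producing BioNLP shared-task style typed events: a trigger span plus
Theme/Cause arguments) with a translation step from event types to BEL
functions. A known obstacle is coreference: when a sentence says "... and
targets *it* for degradation", the event extractor sees a pronoun where it
needs a gene mention, and the relation is lost. belminer implements the
full surrounding machinery — a rule-based coreference resolver and text
substituter, standoff event I/O, the event-to-BEL translation with entity
normalization, and the six-level evaluation scheme used by the BioCreative
BEL track — with event extraction itself deliberately out of scope: events
are an input artifact, so any extractor emitting standoff files can be
plugged in.

## Coreference resolution

Anaphor detection covers personal pronouns (*it*, *they*), possessive
pronouns (*its*, *their*) and definite noun phrases whose head is a
domain noun (*the protein*, *these genes*; default domain nouns: gene,
protein, receptor, molecule and their plurals). Relative pronouns are
detected only when explicitly enabled and are off by default: resolving
them degrades event identification, so the default configuration leaves
them alone.

Antecedent selection considers every noun phrase that ends before the
anaphor starts, within the anaphor's sentence and a window of preceding
sentences, and applies three rules:

1. **Number agreement.** Candidates disagreeing in grammatical number are
   removed. Number is resolved in a fixed order: explicit annotation, then
   a closed-class lexicon (*it/its/this* singular; *they/their/these/those*
   plural), then a terminal-*s* heuristic on common nouns, else *unknown* —
   and *unknown* is compatible with everything, because the rule is a
   filter and filtering on missing evidence would over-prune.
2. **Gene/protein gate (definite NPs only).** A definite-NP anaphor keeps
   only candidates overlapping a gene/protein mention. Overlap (rather
   than exact coincidence) is used because NER spans and NP spans rarely
   align exactly.
3. **Proximity.** The closest surviving candidate wins. Distance is the
   character gap between candidate end and anaphor start; ties on
   identical end offsets go to the longer candidate. Both choices are
   arbitrary but deterministic, which matters more than the particular
   convention: resolution must be reproducible.

Design choices the source material leaves open, fixed here: the candidate
window defaults to the current sentence plus **2** preceding sentences
(covers the worked cross-sentence cases while bounding the search);
possessive pronouns are rewritten with a genitive marker (`'s`, or a bare
`'` after a terminal *s*), configurable.

Substitution replaces each anaphor span with its antecedent's surface
text, right-to-left so earlier offsets stay valid, and records a segment
offset map. The map is the load-bearing piece: extraction runs on resolved
text, but gold offsets live on the original text, so every downstream span
must be projectable back. Copied regions project by an offset shift;
spans entirely inside a substituted region project to the antecedent's
source span (whose surface equals the substituted surface); spans
straddling a substitution boundary are flagged unmappable rather than
silently misplaced.

```{r coref-example}
doc <- read_document(system.file("extdata", "mdm2_example.json",
                                 package = "belminer"))
links <- resolve_coreference(doc)
sub <- substitute_coreferences(doc, links)
sub$resolved_text
```

## From events to BEL statements

Simple event types map to term shapes:

| Event type          | BEL term                              |
|---------------------|---------------------------------------|
| Protein_catabolism  | `deg(p(X))`                           |
| Gene_expression     | `r(X)`                                |
| Transcription       | `r(X)`                                |
| Phosphorylation     | `p(X, pmod(P))`                       |
| Localization        | `tloc(p(X))`                          |
| Binding, ≥ 2 Themes | `complex(p(A), p(B), ...)`            |
| Binding, 1 Theme    | `p(A)`                                |

Regulation events supply the statement skeleton. `Positive_regulation`
becomes `increases` and `Negative_regulation` becomes `decreases`,
with trigger lexicons available for polarity-sensitive behaviour; when the
`act()` extension is enabled, a `Positive_regulation` whose trigger is an
activation word (*activation*, *activated*, ...) wraps the object term in
`act()` instead (the relationship stays `increases`: activation asserts a
positive effect on the activity). The bare `Regulation` type is skipped as
inherently ambiguous. A regulation event lacking a Cause yields no
statement; event-valued arguments are mapped recursively to their term
only — the single relationship always comes from the outermost regulation.
Whether the nested object keeps its modifier under the relationship (i.e.
`... increases deg(p(X))`) is resolved here in the affirmative: the
modifier is part of the Theme's meaning and dropping it would conflate
degradation with abundance.

The trigger lexicons ship with the attested seeds (*targets* positive,
*down-regulator* negative, *activation/activated* for the `act()`
extension) plus ordinary polarity verbs; all three sets are plain word
lists and are meant to be extended per corpus.

Each statement carries a confidence score: the geometric mean of the
trigger and argument probabilities over the event and its nested events.
No formula is prescribed by the original system description; the geometric
mean is chosen because it is 1 exactly when no confidence information is
present, monotonically non-increasing in every added probability, and
scale-balanced between trigger and argument evidence. The conversion
threshold defaults to 0 (keep everything, report scores).

## Entity normalization

Mentions are matched exactly — after trimming, whitespace collapsing and
case folding — against lexicon fields in the priority order symbol >
synonyms > alternative names > description, over an ordered lexicon list
(first lexicon with a hit wins; remaining ties break by lexicographic
identifier). Case folding is deliberate: strictly byte-exact matching is
internally inconsistent with gene nomenclature conventions, where the same
mention surfaces as *IL-4*, *Il4* or *IL4* depending on species styling. A
`strict` flag restores byte equality. Statements containing any mention
that fails to normalize are dropped whole and logged: a partially
grounded statement is not a BEL statement.

## The six evaluation levels

Predictions are scored per sentence against gold at six levels, with
micro aggregation (counts summed over sentences before computing
precision, recall and F, matching how the track reports corpus tables):

* **Term (T)** — every entity occurrence as a triple (abundance function,
  namespace, identifier). Activity wrappers and `pmod` are not part of the
  term item.
* **Function (F)** — every occurrence of a Table-2 function (`complex`,
  `pmod`, `deg`, `tloc`, `act`): the function together with its abundance
  argument including namespace and identifier.
* **Secondary Function (Fs)** — the function with the abundance function
  of its argument, ignoring the entity's namespace and identifier.
* **Relation (R)** — subject, relationship and object all correct, where
  subject/object are compared at the entity level (wrappers and `pmod`
  ignored): a missed `deg()` breaks the Statement level but not the
  Relation level.
* **Secondary Relation (Rs)** — at least two of the three components
  correct. Full matches are included as true positives (forced by the
  published count tables, where Rs ≥ R everywhere, although only the
  partial cases are enumerated in prose).
* **Statement (S)** — the full canonical statement.

Two tolerances mirror the track's conventions: an ortholog map declaring
identifier equivalences across HGNC/MGI/EGID (closed symmetrically and
transitively with union–find), and function equivalence folding `kin`,
`tscript` and `cat` into `act`.

Matching is one-to-one per level. Where item equality is an equivalence
relation (T, Fs, F, R, S) the true-positive count is the multiset
intersection; the Rs predicate ("≥ 2 of 3") is not transitive, so greedy
matching can be suboptimal there, and the scorer instead computes a
maximum bipartite matching (Kuhn's augmenting paths — sentences carry a
handful of statements, so exactness is cheap). The test suite verifies
the matcher against exhaustive enumeration on a thousand random sentence
pairs.

Reported P/R/F are percentages rounded half-up to one decimal, the
convention of the printed tables; F is computed from counts as
`100·2tp/(2tp+fp+fn)`, which equals the harmonic mean of P and R whenever
both are defined, including before rounding.

### Paired significance testing

Two systems are compared with a paired t-test over per-group F-scores:
the corpus (in sorted sentence-id order) is split into k contiguous,
nearly equal groups, each group's F computed from its summed counts, and
`t = mean(d)/(sd(d)/sqrt(k))` with `df = k − 1`. The grouping unit is not
recorded in the track material; k defaults to 30 (df = 29, the printed
critical value ±1.699 ≈ the one-sided 5% Student quantile, which the
implementation recomputes via `qt`). Zero-variance differences yield
±∞ with a flag rather than an error.

## The synthetic corpus generator

Real BEL-track corpora and the upstream extractor are external, so the
package ships a generator that plants everything the pipeline consumes:
annotated sentences built from template frames (degradation, expression,
phosphorylation, binding, localization, inhibition, activation), entity
mentions backed by a generated lexicon (with hyphenated synonym surfaces
exercising normalization), standoff events for two extraction conditions,
gold statements written directly from the frame templates (independently
of the conversion code, so pipeline recovery is a genuine closure
property), and coreference links with known answers.

A unit is either within-sentence or cross-sentence. Cross-sentence units
put the causing entity in a preceding sentence and reach it through a
planted anaphor whose kind is sampled from a configurable mix (default
proportions follow the anaphor-type composition observed in the BEL-track
training data, 257:411:507 for personal/possessive/definite-NP). The
antecedent sentence carries a plural, non-NER distractor phrase so that
exactly one candidate survives the resolution rules — planted links are
recoverable by construction, which is what makes 100%/0% recovery
contrasts meaningful. The two event conditions encode what an extractor
would see: over resolved text the Cause is present; over original text
the pronoun is not an entity, so the regulation event lacks its Cause and
produces no statement.

What the generator does **not** emulate: real syntactic variety,
ambiguous antecedents, NER errors, extraction noise, nested discourse, or
entity types beyond genes/proteins. Perfect pipeline scores on synthetic
corpora therefore validate the machinery (offset bookkeeping, rule
application, mapping, normalization, scoring), not real-corpus accuracy —
on real track data this class of system scores in the 20–35 F range at
the statement level.

Determinism: the seed fully determines the output; the generator saves
and restores the caller's RNG state.

```{r generator-example}
corpus <- generate_corpus(fixture_spec(seed = 1, n_sentences = 20,
                                       cross_sentence_rate = 0.5))
on  <- run_corpus_pipeline(corpus, coref = TRUE)
off <- run_corpus_pipeline(corpus, coref = FALSE)
rbind(coref = on$report$levels[on$report$levels$level == "S", -1],
      no_coref = off$report$levels[off$report$levels$level == "S", -1])
```

## Numerical and degenerate-input conventions

* Offsets are 0-based, half-open, document-global — the standoff
  interoperability convention; all modules inherit it.
* Empty denominators in P/R/F yield 0, not NaN.
* `score_corpus` unions the gold and prediction sentence-id sets; a
  sentence missing on one side scores against an empty list.
* Duplicate sentence ids within one input map are an error (grouping is
  the caller's job, done by `read_bel_tsv`).
* Canonical BEL serialization: short-form function names, no space after
  commas, quotes only around whitespace-bearing identifiers, `complex`
  members sorted lexicographically; parsing then serializing is
  idempotent.
* Statement confidence is carried as a side channel and never serialized
  into BEL text.
* Problem sizes in the shipped tests and acceptance script — 240-sentence
  pipeline corpora, 120-sentence parameter-recovery corpora, 1000-sample
  matcher and round-trip checks, a 1000-anaphor mix check — were chosen as
  the smallest sizes at which the sampling-based checks are statistically
  meaningful.

## Known limitations

* Gene/protein entities only; diseases, chemicals and processes pass
  through the BEL model but are not produced by the converter.
* Exact-match normalization: no fuzzy matching, species inference or
  cross-namespace identifier mapping (the evaluator's ortholog table
  handles equivalence at scoring time instead).
* The bare `Regulation` event type is always skipped.
* No appositive or nominal coreference beyond definite NPs; no
  cross-document coreference.
* The evaluator mirrors the track's published semantics but is not a
  byte-for-byte reimplementation of the official web service; its open
  parameters (aggregation, t-test grouping, Rs tie-breaking) are fixed to
  the choices documented above.
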
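---
title: "Compiling and auditing Clinical Evidence Logic Statements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling and auditing Clinical Evidence Logic Statements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celsify)
```

## The problem

Evidence libraries for imaging appropriateness collect recommendations
from guidelines, clinical decision rules, and local best practice, each
reduced to a Clinical Evidence Logic Statement (CELS): a one-line
condition–action rule such as `If [Suspected PE] Then [VQ SPECT]` or
`If [Alvarado score* <4] Then Not [CT Abdomen]`. For a CELS to travel
between clinical decision support systems it must be re-expressed in
interoperability standards: SNOMED CT for the clinical terms, CQL for
the condition logic, and a FHIR decision-support-rule XML document tying
the action to the logic. This package mechanizes that translation and —
just as importantly — audits where it fails, because a substantial share
of realistic statements cannot be fully represented in these standards.

`celsify` deals with three artifacts per statement: the parsed CELS, a
six-section CQL library, and a five-element decision-rule XML document.
A corpus-level audit classifies every statement as fully represented,
partially represented because of terminology (a term with no concept
mapping), or partially represented because of CQL (an action with a
future temporal component).

## The DSL and its grammar

The statement grammar is

```
If <clause> ((And|Or) <clause>)* Then [Not] [<action>]
clause  := [Not] "[" term [comparator number [unit]] [past-lookback] "]"
```

Design choices worth knowing:

* **Connectives are left-associative with no precedence and no
  parentheses.** The statements this DSL models are flat conjunctions in
  practice; `Or` is accepted for completeness but mixing `And`/`Or`
  cannot express grouped logic. This is a documented limitation, not an
  oversight — a statement needing grouping should be authored as a
  decision tree instead.
* **`Then Not` is polarity, not negation of the procedure.** It marks
  the procedure as inappropriate; the action term itself is unchanged,
  which is what lets the XML emitter choose between the two action
  strings "Rule can be applied" and "Rule cannot be applied".
* **A trailing asterisk on a term** (`Alvarado score*`) is the
  conventional annotation for a term known to lack a mapping. The parser
  strips it into a `flagged` field; actual mapping status is decided
  only by the terminology module, so an unannotated term that fails to
  map and an annotated one audit identically.
* **Term storage is case-preserving, comparison case-insensitive**,
  after trimming and whitespace collapsing. There is deliberately no
  fuzzy or synonym matching: substituting a near-synonym can change the
  meaning of a recommendation, so it is left as a human curation step.
* **Numbers are decimals; units are uninterpreted tokens** (`mm` in
  `[nodule size <=4mm]` is carried through verbatim, never converted).

Serialization is canonical, and `parse_cels(serialize_cels(x))` is the
identity on structure (identifier and metadata are not carried by the
line). The test suite checks this round trip on 1000 generated
statements, plus determinism of parsing.

## Temporal components

Time enters the logic in two asymmetric ways:

* **Past lookbacks on conditions** — `[CT chest in the past 12 months]`
  — are representable: they compile to a lookback clause inside the
  condition's define.
* **Future schedules on actions** — `CT chest in 12 months`, windows
  like `in 6-12 months`, multi-point schedules like `in 3 months, 9
  months, And 24 months`, and recurrences like `annually for 3 years` —
  are *not* representable: CQL has no construct for running an action at
  a future time, and the decision-rule XML has no future temporal
  element. The auditor detects these (`detect_future_temporal()`) and
  flags the statement `partial_cql`; the CQL emitter refuses them.

Internally a temporal specification stores a direction (`past`/`future`)
and either a recurrence (interval and total duration, in months) or a
list of month segments, each a `(lo, hi)` pair; the derived
`window_min_months`/`window_max_months`/`points` fields summarize the
segments. Mixed phrases (`in 9-12 months And 24 months`) keep their
segment structure so they re-render verbatim. A phrase that looks
temporal but does not parse (`in a few months`) is reported as a
`raw_unparsed` finding rather than silently ignored; months are the only
unit modeled, matching how surveillance intervals are written in
imaging guidance.

## Terminology and value sets

A terminology subset is a table mapping normalized surface terms to one
(precoordinated) or several (postcoordinated) concept identifiers, plus
an optional acyclic is-a hierarchy. Value sets are either extensional
(an enumerated id list) or intensional (a root concept plus all
hierarchy descendants; expansion is root-first, descendants sorted by
id, so output is stable).

Unmapped terms are classified by a packaged lexicon of common-English
tokens: a term containing such a token ("vehicle rollover", "new
feature") is an `english_phrase` failure, everything else ("Alvarado
score", "Revised Geneva score") a `clinical_term` failure. This is a
deterministic stand-in for a judgement call — it reproduces the
canonical split of failure examples, but a richer classifier would need
linguistic resources out of scope here.

The packaged terminology (`inst/extdata/terminology_synthetic_subset.tsv`)
contains the published concept id `417113001` for "suspected PE"; every
other id in it, and the whole hierarchy table, are synthetic
placeholders — enough to compile the worked examples without shipping
any licensed terminology content. Named score terms are deliberately
absent, with a sidecar list (`known_gaps.txt`) used by tests. The
packaged subset also maps "high risk"/"low risk" so that the
nodule-surveillance examples isolate the temporal failure mode; in a
real SNOMED CT deployment such qualifier phrases are themselves
problematic (see limitations).

## Logic variants

Evidence units come in three shapes. Single-decision units are one
CELS. Branching units are authored as binary decision trees;
`flatten_decision_tree()` emits one CELS per leaf, conditions being the
root-to-leaf path with false-branch conditions negated at the condition
level (the grammar's `Not`), leaves ordered depth-first with the true
branch first. Score-based units are bands over an evidence score;
`expand_score_rule()` emits one CELS per band, an included bound
rendering as `>=`/`<=` and an excluded one as `>`/`<`, so the band
`[4, 6]` prints as the familiar `>=4 And <=6`. Bands must be pairwise
non-overlapping; a brute-force sweep in the tests checks that exactly
one band fires for every integer score.

A note on source imprecision: branching units are described as yielding
"more than two" statements, but a two-leaf tree yields exactly two. No
minimum is enforced here.

## Emitters

The CQL document has the six customary sections in fixed order:
Library, Using (the QUICK data model, version pinned), Code System
(SNOMED CT), Value Set (one extensional set per distinct condition
term, members inline), Context (always `Patient` — the logic references
patient-level data), and Defines. Each condition becomes one define
named by slugifying its term (de-duplicated with numeric suffixes); the
final define, `MeetsInclusionCriteria`, conjoins every condition define
with the statement's connectives and is the name the XML document
references. Retrieve expressions are opaque templated strings
(`exists ([Condition: "Suspected PE"])`); no CQL engine execution or
type checking is attempted, so the emitted text is a faithful structural
rendering, not a validated executable library.

The XML document has exactly five elements — `action`, `condition`
(referencing the final define via its `value` attribute),
`moduleMetadata` (title, authors, year, evidence kind), `library`, and
`trigger` (the ordered procedure; trigger semantics belong to the
implementation environment, so it is an opaque string). Rendering is
deterministic: fixed element order, two-space indent, UTF-8, escaped
content — byte-identical across runs, and validated against the
packaged XSD. Bundling an evidence unit writes one `.cql`/`.xml` pair
per statement plus a JSON manifest.

## The audit and its arithmetic

`audit_cels()` computes three non-exclusive flags: `partial_snomed`
(some condition or action term unmapped — the action term is looked up
with its temporal phrase stripped, since "CT chest" may map even when
"in 6-12 months" is inexpressible), `partial_cql` (a future temporal
finding), and `fully_represented` (neither). Because the flags are
non-exclusive, corpus category counts may sum to more than the total;
the report prints each category independently. Percentages are
`100·n/total` rounded **half-up** to one decimal — chosen over base R's
half-to-even so that tallies match the convention used in published
summary tables; an integer-arithmetic oracle in the tests pins this
down. The separate action-term metric is the fraction of statements
whose action procedure term maps, independent of temporal findings.

## The synthetic-corpus generator

`generate_corpus(n, frac_unmapped, frac_temporal, seed)` emulates a
graded evidence corpus: statements with 1–3 conditions drawn from a
fixed imaging vocabulary (every term mapped in the returned
terminology), occasional comparators, negations, units, past lookbacks,
and `Or` connectives; and it **plants** failures in exact integer
numbers — `floor(frac·n)` statements get an out-of-vocabulary term
(from the named-score and English-phrase pools), `floor(frac·n)` get a
future temporal action. Planting is exact rather than Bernoulli so the
auditor must reproduce the counts exactly, not within sampling error.
Temporal failures are planted inside the unmapped subset by default
(`nested = TRUE`), consistent with an overall accounting where
fully-represented and terminology-limited statements partition the
corpus; independent planting is available. The `unmapped_slot` switch
plants the unmapped term in a condition or in the action, the latter
driving the action-term representability metric.

What the generator does *not* emulate: real corpora have correlated
terms, repeated evidence sources, non-uniform statement lengths, and
messier free text. Passing audits on planted corpora shows the
accounting is exact, not that the terminology coverage of any real
library is reproduced; real headline rates depend on the actual
terminology subset used.

Problem sizes used by the tests and the acceptance script — corpora of
765 (mirroring the documented library size), 1000 for round-trip
checks, 20 parameterizations of 40–120 statements for audit-vs-truth —
run in seconds on one CPU.

## Numerical and degenerate-input choices

* Percentages: half-up at one decimal via scaled `floor(x·10 + 0.5)`,
  with a 1e-9 epsilon so fractions specified as `k/n` survive IEEE
  rounding; the same epsilon guards the generator's `floor(frac·n)`.
* Empty condition lists, unbalanced brackets, missing `Then`, unknown
  comparators, and dangling connectives are parse errors naming the
  offending span; an empty corpus is an audit error; an empty evidence
  unit bundles to an empty manifest (not an error).
* A single-leaf tree flattens to one statement with the vacuous
  condition "Any patient" so the output is still grammatical.
* Duplicate condition terms within a statement get de-duplicated define
  names (`NoduleSize`, `NoduleSize2`) and a single audit reason.
* Score bands at a shared endpoint may touch only if at most one side
  includes the endpoint.

## Known limitations

* No natural-language extraction: turning guideline prose into CELS is
  human work upstream of this package.
* Exact-match terminology lookup only; synonym substitution and the
  authoring of real value sets for qualifier phrases like "high risk"
  are curation tasks the audit purposely surfaces rather than solves.
* The emitted CQL is structurally faithful but not executed or
  type-checked against a CQL engine, and the QUICK retrieve bodies are
  templates.
* The XML element set is pinned to a local schema rather than tracking
  a live FHIR release; JSON and Turtle renderings are not provided.
* Temporal parsing covers month-based windows, schedules, and yearly
  recurrences; other units or free-text schedules surface as
  `raw_unparsed` findings.
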
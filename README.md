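# celsify

Compile and audit "If–Then" Clinical Evidence Logic Statements (CELS).

Evidence-based imaging recommendations — "use VQ SPECT in patients with
suspected pulmonary embolism", "do not order CT abdomen when the Alvarado
score is below 4" — can be written as one-line logic statements:

```
If [Suspected PE] Then [VQ SPECT]
If [Alvarado score* <4] Then Not [CT Abdomen]
```

To be shareable across clinical decision support (CDS) systems, each
statement has to be expressed in established interoperability standards:
its clinical terms mapped to SNOMED CT concept identifiers, its
condition logic written as a Clinical Quality Language (CQL) library,
and the rule packaged as a FHIR decision-support-rule XML artifact.
Not every statement survives this translation: named scores ("Alvarado
score") may have no concept in the terminology, ordinary English phrases
("vehicle rollover") are not clinical concepts, and an action scheduled
at a future time ("CT chest in 6-12 months") has no CQL representation
at all. `celsify` is a compiler and auditor for this pipeline, for
informaticists curating evidence libraries: it parses the CELS DSL,
maps terms against a terminology subset, emits the CQL and XML
artifacts for statements that compile, and reports exactly why the rest
do not.

## What it does

* **DSL** — parse and serialize statements of the grammar
  `If <clause> ((And|Or) <clause>)* Then [Not] [action]`, with
  comparators (`[nodule size <=4mm]`), negation, past lookbacks
  (`[CT chest in the past 12 months]`) and future action schedules
  (`[CT chest in 6-12 months]`, `[Low-dose CT annually for 3 years]`).
* **Terminology** — exact-match lookup of surface terms to
  precoordinated (one concept id) or postcoordinated (several ids)
  matches; extensional and intensional (hierarchy-closure) value sets.
* **Logic variants** — classify evidence units as single-decision,
  branching, or score-based; flatten binary decision trees into one
  CELS per leaf; expand banded score rules into one CELS per band.
* **Emitters** — a six-section CQL library (Library, Using, Code
  System, Value Set, Context, Define) per statement, and a five-element
  decision-rule XML document (`action`, `condition`, `moduleMetadata`,
  `library`, `trigger`) validated against a packaged schema.
* **Audit** — per-statement representability flags
  (`fully_represented`, `partial_snomed`, `partial_cql`) with a
  three-way failure taxonomy (`clinical_term`, `english_phrase`,
  `temporal_action`), and corpus-level tallies with half-up-rounded
  percentages.
* **Synthetic corpora** — a seeded generator that plants exact numbers
  of failures, so audit output can be checked against ground truth.

## Worked example

```r
library(celsify)

ex <- paper_examples()                     # packaged examples + terminology
x  <- parse_cels("If [Suspected PE] Then [VQ SPECT]")

audit_cels(x, ex$terminology)
#> <audit> if-suspected-pe-then-vq-spect: fully represented

doc <- emit_cql(x, ex$terminology)
cat(render_cql(doc))
#> // cql-version 1.4
#> library IfSuspectedPeThenVqSpect version '1.0.0'
#>
#> using QUICK version '3.3.0'
#>
#> codesystem "SNOMED-CT": 'http://snomed.info/sct'
#>
#> valueset "Suspected PE": { '417113001' }
#>
#> context Patient
#>
#> define "SuspectedPE":
#>   exists ([Condition: "Suspected PE"])
#>
#> define "MeetsInclusionCriteria":
#>   "SuspectedPE"

elm <- emit_elm(x, doc, meta = source_meta("VQ SPECT for suspected PE"))
cat(render_xml(elm))
#> <?xml version="1.0" encoding="UTF-8"?>
#> <decisionSupportRule>
#>   <action>Rule can be applied</action>
#>   <condition value="MeetsInclusionCriteria"/>
#>   ...
#>   <library>IfSuspectedPeThenVqSpect</library>
#>   <trigger>VQ SPECT</trigger>
#> </decisionSupportRule>
```

The value set carries the SNOMED CT concept `417113001` ("suspected
pulmonary embolism", a precoordinated match); the final define names
the conjunction of conditions that must hold for the rule to fire, and
the XML action says the ordered procedure is appropriate. A statement
that does not compile is explained instead:

```r
print(audit_cels(ex$alvarado[[2]], ex$terminology))
#> <audit> alvarado-L4: partial (terminology)
#>   - clinical_term: Alvarado score

report <- audit_corpus(c(list(ex$pe), ex$alvarado, ex$fleischner), ex$terminology)
print(report)
#> <corpus report> N=7
#>   CELS fully represented using SNOMED CT, CQL, and FHIR     1 (14.3%)
#>   CELS partially represented using SNOMED CT                3 (42.9%)
#>   CELS partially represented due to CQL                     3 (42.9%)
#>   Action terms representable                                7 (100.0%)
```

## Command line

```sh
Rscript inst/cli/celsify.R compile --terminology terminology.tsv --out artifacts/ corpus.cels
Rscript inst/cli/celsify.R audit   --terminology terminology.tsv --out report/   corpus.cels
Rscript inst/cli/celsify.R generate --n 765 --frac-unmapped 0.82 --seed 7 --out corpus/
```

Exit codes: 0 success, 1 usage error, 2 parse/compile failure.

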
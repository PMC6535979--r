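Package: celsify
Title: Compile and Audit If-Then Clinical Evidence Logic Statements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with Clinical Evidence Logic Statements
    (CELS), the "If [condition] Then [action]" units used to encode
    imaging-related clinical recommendations for decision support. The
    package parses a small CELS domain-specific language, maps clinical
    surface terms to a SNOMED CT-style terminology subset with
    extensional and intensional value sets, expands branching decision
    trees and score-based rules into flat CELS sets, emits Clinical
    Quality Language (CQL) libraries and decision-support-rule XML
    artifacts, and audits corpora for representability: which statements
    compile fully, which fail on unmapped terminology, and which fail
    because their action carries a future temporal component that the
    CQL/ELM framework cannot express. A seeded synthetic-corpus
    generator with planted ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
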
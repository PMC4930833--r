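Package: belminer
Title: Coreference-Aware Extraction and Evaluation of Biological Expression Language Statements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for turning biomedical event annotations into Biological
    Expression Language (BEL) statements. Provides a data model and JSON I/O for
    annotated sentences (tokens, noun phrases, gene/protein mentions), rule-based
    anaphora resolution with coreference substitution and an offset map, a reader
    and writer for BioNLP shared-task standoff event files, a parser and canonical
    serializer for the BEL-track subset of BEL, event-type to BEL-function
    translation with trigger lexicons for regulation polarity, dictionary-based
    entity normalization, a six-level precision/recall/F evaluator with ortholog
    and function-equivalence tolerances and a paired t-test for system comparison,
    and a deterministic synthetic corpus generator with planted coreference links
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
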
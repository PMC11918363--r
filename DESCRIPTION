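Package: kgfuse
Title: Knowledge-Graph Fusion Models for Adverse Drug Event Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting adverse drug event (ADE) spans in text with
    knowledge-fusion sequence labelers. Converts drug and symptom ontologies
    (OWL or OBO) into directed class graphs, learns node embeddings with a
    graph attention network trained on top-level node classification or link
    prediction, tags drug and symptom mentions with a rule-based lexicon
    tagger, aligns node embeddings to a transformer encoder's wordpiece grid,
    and concatenates them with contextual token states to feed a three-class
    IOB head. Includes the full experimental protocol (document-level splits,
    AdamW training, TPE-style hyperparameter search, final retraining),
    strict and relaxed span-level evaluation, corpus characterization
    statistics, readers and writers for CoNLL-IOB, brat standoff and JSONL
    annotation formats, and generators for synthetic ontologies and annotated
    corpora with controllable entity co-occurrence structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
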
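Package: biocoref
Title: Protein Coreference Resolution for Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Resolves anaphoric coreference to protein mentions in biomedical
    text annotated in BioNLP-ST standoff format. Provides a deterministic
    rule system (syntactic shortest-path resolution for relative pronouns,
    coordination-aware resolution for personal pronouns, semantic constraints
    for definite noun phrases), a mention-pair LSTM sequence classifier with
    skip-gram mention embeddings trained on the task corpus, a link-level
    scorer with a five-category error audit, and a deterministic synthetic
    annotated-corpus generator for parser-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
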
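Package: kiddi
Title: Knowledge-Infused Disease Diagnosis from Doctor-Patient Dialogues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for diagnosing a patient's disease from an annotated
    doctor-patient dialogue by fusing two evidence channels: a
    transformer-style encoding of the conversation (self-report and full
    dialogue) and a graph-attention embedding of a symptom-symptom-disease
    knowledge graph weighted by symptom frequency-inverse disease frequency
    (sf-idf). Includes a corpus data model with JSON serialization, a
    synthetic dialogue generator with planted symptom-disease structure,
    knowledge-graph construction, discourse-aware selective filtering of
    per-conversation subgraphs, a compact trainable model (graph attention
    layers, additive attention fusion, softmax classifier) with exact
    analytic gradients, a training and evaluation harness with ablation
    modes and hierarchical classification, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
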
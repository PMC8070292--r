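Package: litkn
Title: Knowledge Networks and Time-Resolved Proximity Analysis from Plant
    Science Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A dictionary-based literature-mining pipeline that turns a corpus
    of plant-science texts into genotype-phenotype knowledge networks. Provides
    sentence segmentation, lexicon-driven named entity recognition over a
    three-entity type system (gene/protein, metabolite, trait), within-sentence
    relation extraction, rule-based normalization of entity labels to preferred
    forms, knowledge-triple CSV export, construction of undirected
    co-occurrence networks weighted by document frequency, and a cumulative
    time-sliced shortest-path analysis that flags candidate gene-trait
    associations before they are stated explicitly. Includes a synthetic-corpus
    generator with planted relation schedules for end-to-end validation, and
    span-level precision/recall/F1 scoring of entity annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
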
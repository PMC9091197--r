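Package: herbnet
Title: Herb-Molecular Relation Extraction and Knowledge Graph Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds evidence-backed herb-chemical-gene-disease knowledge
    graphs from annotated biomedical abstracts. Parses and writes the
    PubTator annotation exchange format, encodes a four-entity-type /
    five-relation-type herb ontology with NER post-adaptation and corpus
    screening, constructs six-class sentence-pair relation-extraction
    datasets (positive extraction, typed negative sampling, stratified
    splits), trains a from-scratch transformer encoder relation classifier
    with masked-language-model domain fine-tuning and exhaustive
    hyperparameter grid search, augments training data by entity-placeholder
    template substitution, evaluates predictions with table-compatible
    per-class and macro metrics, average precision and occlusion-based token
    attribution, and assembles extracted triplets into a typed knowledge
    graph supporting degree rankings, evidence queries, herb similarity and
    gene-mediated drug-repurposing candidates. A seeded synthetic-corpus
    generator makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
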
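# herbnet

Herb–molecular relation extraction and knowledge-graph analytics in R.

Modern pharmacognosy abstracts report which chemicals a herb contains,
which genes those chemicals act on, and which diseases respond. `herbnet`
turns entity-annotated abstracts (PubTator exchange format) into an
evidence-backed knowledge graph over a four-type ontology — Herb,
Chemical, Disease, Gene — with five typed relations:

    HHC (Herb, Chemical)    herb has compound
    HTD (Herb, Disease)     herb treats disease
    CAD (Chemical, Disease) chemical acts on disease
    CAG (Chemical, Gene)    chemical associates gene
    GID (Gene, Disease)     gene influences disease

The pipeline covers every stage:

* **PubTator I/O** — parse, validate and write the four-section annotation
  format, with offset invariants checked (`parse_pubtator`,
  `validate_document`, `write_pubtator`);
* **ontology & screening** — typed relation signatures, raw-NER adaptation
  (vocabulary species → herbs, mutations/cell lines dropped), abstract
  screening against a curated term list;
* **dataset construction** — six-class sentence-pair examples (sentence A =
  title ⊕ abstract, sentence B = head ⊔ tail), typed negative sampling,
  stratified 3:1 splits, per-label statistics;
* **relation classifier** — a from-scratch transformer encoder
  (embeddings → multi-head self-attention stack → dense + softmax) with
  plain/weighted cross-entropy, SGD/momentum/Adam, masked-language-model
  domain fine-tuning, and an exhaustive 150-point hyperparameter grid
  search ranked by macro-F1; external pretrained checkpoints plug in where
  a BERT-family model would;
* **substitution augmentation** — entity mentions → type placeholders,
  template generation (pluggable; default seeded fragment recombination),
  placeholder realization with known related pairs, labels sound by
  construction;
* **evaluation** — confusion matrices and per-class/macro precision,
  recall and F1 under the published report conventions (`TN_k = trace −
  TP_k`, macro Total column, half-up one-decimal display), step-sum average
  precision, and occlusion-based token importance `d_i = c* − c_i`;
* **knowledge graph** — deduplicated typed entities and relations with
  per-article evidence sentences and support counts, degree rankings,
  evidence queries, herb similarity
  `sim(i,j) = ½(J(SG_i, SG_j) + J(SD_i, SD_j))` (Jaccard over reachable
  gene sets and treated disease sets), and gene-mediated drug-repurposing
  candidates;
* **synthetic corpus generator** — seeded documents with planted entities,
  relations and cue words plus the ground-truth graph, so the whole
  pipeline is testable offline.

## Worked example

```r
library(herbnet)

cp <- generate_corpus(generator_spec(seed = 42, n_docs = 12))
ex <- rbind(build_examples(cp$docs), sample_negatives(cp$docs, 2, seed = 42))
sp <- split_train_test(re_examples(ex), seed = 42)
compute_stats(sp)
#>        HHC  HTD CAD CAG GID Neg
#> train  7.0  6.0 3.0 1.0 2.0  18
#> test   3.0  2.0 0.0 0.0 0.0   6
#> total 10.0  8.0 3.0 1.0 2.0  24
#> pct   20.8 16.7 6.3 2.1 4.2  50

kg <- assemble_graph(cp$docs)
kg
#> <knowledge_graph: 40 entity(ies) [Chemical 13, Disease 9, Gene 7, Herb 11], 24 relation(s)>
```

The counts row shows the per-label train/test partition of the 48
generated examples and each label's share of the total; the graph
summary counts the deduplicated typed entities and evidence-backed
relations recovered from the corpus (exactly the planted ground truth,
`cp$truth`).

Feeding the evaluation module a prediction list produces the published
report layout — counts, the trace-based TN convention, and half-up
percentages with a macro Total column:

```r
cm <- confusion_matrix(gold, pred)     # six-class label vectors
class_metrics(cm)
#>       CAG   HHC   HTD   CAD   GID   Neg Total
#> TP     13   338   191    64    25   220   851
#> ...
#> F1  83.9% 97.4% 95.3% 90.8% 89.3% 98.9% 92.6%
```

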
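---
title: "From annotated abstracts to herb-molecular knowledge graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From annotated abstracts to herb-molecular knowledge graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The problem

Modern pharmacognosy papers routinely report which chemicals a medicinal
plant contains, which genes those chemicals act on, and which diseases
respond — but the findings are scattered across abstracts. `herbnet`
implements a pipeline that turns entity-annotated abstracts into an
evidence-backed knowledge graph over four entity types (Herb, Chemical,
Disease, Gene) and five typed relations:

| label | meaning                  | signature            |
|-------|--------------------------|----------------------|
| HHC   | herb has compound        | (Herb, Chemical)     |
| HTD   | herb treats disease      | (Herb, Disease)      |
| CAD   | chemical acts on disease | (Chemical, Disease)  |
| CAG   | chemical associates gene | (Chemical, Gene)     |
| GID   | gene influences disease  | (Gene, Disease)      |

A sixth pseudo-label `Neg` marks type-compatible entity pairs with no
relation, making relation extraction a six-class sentence-pair
classification problem. Named entity recognition is consumed, not
performed: documents arrive in the PubTator exchange format with typed
mentions, and the package's adaptation step maps raw NER tags onto the
ontology (species become herbs when they match a curated domain
vocabulary; mutations and cell lines are discarded as out of ontology).

## Offset conventions

Mention offsets are 0-based and end-exclusive, indexing the concatenation
of title and abstract. The separator between them is configurable
(`sep` argument, default a single space) because circulating files differ
in whether the title's terminal punctuation and separator account for one
or two characters; the package's invariant is checkable either way, since
`validate_document()` verifies that every mention's offsets slice to its
surface form. Validation reports violations as data rather than raising
errors, and relations whose endpoint ids resolve to no mention are flagged
but retained: published excerpts truncate mention lists, and I/O should be
lossless.

## The relation classifier

The classifier is a BERT-shaped transformer encoder implemented from
scratch in R: token, segment and position embeddings feed `N` encoder
layers (multi-head scaled dot-product self-attention, GELU feed-forward,
residual connections with post-layer normalization), the final hidden
states are mean-pooled, and a dense + softmax head produces a normalized
six-way confidence distribution. Sentence A is the title and abstract;
sentence B is the head and tail surface forms joined by one space; a
separator token ends each sentence, and when the pair exceeds the token
budget sentence A is truncated from its tail — titles and openings carry
the finding, and sentence B is never truncated.

Two presets are provided. `encoder_preset("base")` has the standard
12-layer, 12-head, width-768 shape and exists to receive externally
pretrained weights: `train_classifier()` and `domain_finetune_mlm()`
accept a checkpoint (tokenizer plus parameters), which is exactly where a
BERT-family model plugs in. `encoder_preset("tiny")` (2 layers, 2 heads,
width 32, budget 64) trains from scratch in seconds on a CPU and is the
preset every test runs; all capacity and attribution claims in this
package are statements about the tiny preset on synthetic data, not about
pretrained models on real abstracts.

The tokenizer is deliberately simple: whitespace tokens, case preserved,
with five reserved symbols (padding, unknown, separator, mask, and a
never-trained occlusion token). Case-preserving whitespace tokenization
makes detokenization exact — sentence B always survives a round trip —
at the cost of a vocabulary that grows with the corpus. A subword
tokenizer would slot in behind the same three functions.

Training supports plain and class-weighted cross-entropy (weights are
inverse class frequency normalized to mean one — the label distribution
is heavily skewed, with two classes near 35% and one near 1%), and SGD,
SGD with momentum 0.9, and Adam. Everything is deterministic given the
seeds in the configs; there is no dropout, so inference is deterministic
too.

### Domain fine-tuning

`domain_finetune_mlm()` performs masked-language-model training on raw
title+abstract text: 15% of tokens (at least one) are replaced by the
mask token per sequence and the encoder is trained to recover them
through a vocabulary-projection head. The checkpoint records held-out
masked-token cross-entropy before and after; on a 200-document synthetic
corpus, 500 minibatch steps of the tiny preset reduce it by roughly 3
nats. Zero steps provably return the checkpoint unchanged.

### Hyperparameter grid

`grid_configs()` enumerates the tuning ranges — epochs {1, 3, 5, 7, 9},
learning rates {1e-4, 3e-4, 1e-3, 3e-3, 1e-2}, two losses, three
optimizers, 150 points — and `grid_search()` trains every point and ranks
by macro-F1 on an evaluation set, breaking ties toward fewer epochs and
lower learning rates (cheaper and more conservative). The evaluation set
should be a held-out validation split; passing the test set is possible
but leaks test information into selection, so it is never the default.

## Dataset construction

`build_examples()` emits one example per relation annotation, using the
first mention text of each endpoint id as its surface form (reports print
surface forms, not concept ids). `sample_negatives()` draws ordered
within-document entity pairs whose types fit some positive signature but
which carry no annotation — cross-document pairs are never sampled,
because co-occurrence within an abstract is what makes a pair a plausible
but absent relation. The default suggestion for `n_per_doc` is the value
that brings `Neg` near the largest positive class, mirroring the roughly
1:1 ratio of the manually annotated reference dataset.

The 3:1 train:test split stratifies by label: the global quarter is
apportioned across labels by largest remainder on each label's share
(ties resolved in canonical label order), so each label's test count is
within one example of proportional and a 3,536-example multiset yields
exactly 884 test rows. Labels with fewer than four examples go wholly to
training with a warning, since a quarter of three rounds to nothing
useful.

## Substitution-based augmentation

Training data for domain relation extraction is expensive, so the package
implements a two-substitution template pipeline. Substitution I extracts
every sentence containing both endpoints of an annotated relation and
replaces all entity mentions with type placeholders (`[Chemical] induces
apoptosis via inhibition of the [Gene] signaling pathway.`), producing
one template corpus per relation type. A template generator then produces
new templates; the contract requires exactly one head-type and one
tail-type placeholder per output. The default generator recombines
prefix/middle/suffix fragments of corpus templates around the
placeholders — deterministic, dependency-free, and testable — and a
generative language model can replace it behind the same contract, which
is precisely where a fine-tuned GPT-2 sits in the full-scale pipeline.
Substitution II realizes each template with an entity pair whose relation
is already known from the entity database, so the label of every
augmented example is sound by construction: that invariant, not fluency,
is the module's guarantee. Augmented examples carry `origin =
"augmented"` and are only ever appended to training data.

### The augmentation benchmark

The directional claim — augmentation does not hurt — is tested on a
5-examples-per-class training set against a 15-per-class held-out set
over five seeds, comparing mean held-out macro-F1 with and without five
augmented examples per positive class. Both runs train the tiny preset to
convergence (20 epochs) with class-weighted cross-entropy: augmentation
shifts the label mix toward the positive classes, and the weighted
objective is this model family's standard answer to label skew. Short of
convergence the comparison is dominated by noise and by entity-token
shortcuts that the cue words have not yet displaced, which is a statement
about underfit models, not about augmentation.

## Evaluation conventions

`class_metrics()` reproduces the conventions of published six-class
relation-extraction reports exactly, because bit-compatibility with those
tables is the module's acceptance surface:

* per class, TP is the diagonal entry, FP the column residual, FN the row
  residual;
* TN is the number of *correctly classified* instances of the other
  classes, `TN_k = trace - TP_k` — not the standard one-vs-rest count,
  which is available via `tn = "standard"`;
* precision, recall and F1 are percentages; displayed values are rounded
  half-up to one decimal while raw values are kept internally;
* the Total column sums the counts and takes unweighted (macro) means of
  the six per-class percentages.

Average precision follows the step-sum definition
`AP = sum_n (R_n - R_{n-1}) P_n` over the descending-confidence ranking;
multi-class AP is macro one-vs-rest by default (micro is available — the
choice is not standardized in the literature this package follows).
Undefined precision (no predictions for a class) is reported as zero with
an explicit flag rather than NA, matching how the reports tabulate it.

Token importance is occlusion-based: for the first sentence containing
both entity surface forms, each token in turn is replaced by the reserved
occlusion token and the drop in the gold label's confidence,
`d_i = c* - c_i`, is that token's importance. The occlusion token is a
vocabulary entry never seen in training, the closest available
approximation of a "meaningless" token; occluding a token with itself
provably yields zero.

## Knowledge-graph assembly and analytics

`assemble_graph()` deduplicates entities by id and relations by
`(rtype, head, tail)`, attaches the first co-occurrence sentence of each
document as evidence (whole text as a flagged fallback), counts support
as distinct contributing articles, and rejects — with a report — any
triplet violating the ontology signature. On generator output the
assembled edge set equals the planted edge set exactly.

Analytics follow the graph's semantics: herb–gene rankings traverse
herb → HHC → chemical → CAG → gene paths and count distinct partners
(herb–gene shortcuts do not exist in the schema); herb–disease rankings
use direct HTD edges. Herb similarity is the half-sum of two Jaccard
indices, over reachable gene sets and treated disease sets; a term with
an empty union contributes zero and is flagged, keeping the score defined
for sparsely connected herbs. Repurposing candidates for a disease are
the chemicals reaching it through shared GID/CAG genes that lack a direct
CAD edge, ranked by the number of shared genes.

## The synthetic-corpus generator

`generate_corpus()` plants typed entities, relation sentences (entity
pair plus a relation-specific cue word, e.g. `contained` for HHC),
unrelated co-mention sentences, and filler sentences into documents with
exact gold offsets, returning the ground-truth graph alongside. Defaults
are 20 documents, 2 relations per document, entity pools of 12/16/10/10
(herb/chemical/disease/gene), a relation mix proportional to the
reference dataset's imbalanced label distribution, and one unrelated
co-mention sentence per document in expectation. `make_separable_re_set()`
builds sentence-pair examples whose label is a deterministic function of
the cue word, with `Neg` examples cycling through all five type
signatures so entity types alone cannot resolve the label: that makes
classifier capacity (100% training accuracy) and attribution (the cue is
the most important non-entity token) decidable properties.

What the generator does *not* emulate: real linguistic variation,
inter-sentence relations, ambiguous or nested mentions, concept
normalization errors, and realistic vocabulary sizes. Passing tests
therefore demonstrate that the machinery is correct — offsets, labels,
gradients, graph algebra — not that any particular F1 is attainable on
real abstracts; published full-scale scores require the real annotated
dataset and GPU-scale pretrained checkpoints, which are out of scope
here by design.

## Problem sizes

The test suite and the acceptance script run everything from scratch on
CPU: the capacity check trains the tiny preset on 60 examples for 30
epochs; masked-LM fine-tuning uses 200 documents and 500 steps; the
augmentation benchmark runs ten 20-epoch trainings; graph recovery uses
30-document corpora; the average-precision oracle uses 1,000 draws.
These sizes were chosen as the smallest at which each property is
decidable rather than noisy.

## Known limitations

* The whitespace tokenizer has no subword fallback; unseen words collapse
  to a single unknown token.
* Document-level relations whose endpoints never share a sentence get
  whole-document evidence (flagged) and produce no augmentation
  templates.
* The default template generator recombines observed fragments only; it
  cannot produce genuinely novel syntax.
* `grid_search()` trains one model per point sequentially; the 150-point
  grid at realistic scale is a cluster job, not a laptop one.
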
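#' Specification for the synthetic-corpus generator
#'
#' The generator plants typed entities, relation-bearing sentences (entity
#' pair plus a relation-specific cue word) and filler/negative co-mention
#' sentences into PubTator-style documents with exact gold offsets, so every
#' downstream stage is testable without any external corpus. Defaults mirror
#' the imbalanced relation mix of a manually annotated herb relation dataset
#' (HHC and the treated/acting classes dominate; CAG and GID are rare).
#'
#' @param seed integer RNG seed; the corpus is byte-identical given the seed.
#' @param n_docs number of documents.
#' @param vocab_sizes named vector: entity pool size per entity type.
#' @param relation_mix named weights over the five positive labels.
#' @param relations_per_doc planted relations per document.
#' @param filler_sentences filler sentences per document.
#' @param negative_density expected unrelated co-mention sentences per
#'   document (eligible material for negative sampling).
#' @param cue_words named map relation label -> unique trigger word; `Neg`
#'   names the neutral co-occurrence verb.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           n_docs = 20L,
                           vocab_sizes = c(Herb = 12L, Chemical = 16L,
                                           Disease = 10L, Gene = 10L),
                           relation_mix = c(HHC = 0.535, HTD = 0.292,
                                            CAD = 0.106, CAG = 0.020,
                                            GID = 0.048),
                           relations_per_doc = 2L,
                           filler_sentences = 2L,
                           negative_density = 1,
                           cue_words = c(HHC = "contained",
                                         HTD = "treated",
                                         CAD = "attenuated",
                                         CAG = "modulated",
                                         GID = "influenced",
                                         Neg = "accompanied")) {
  stopifnot(all(entity_types() %in% names(vocab_sizes)),
            all(POSITIVE_RELATIONS %in% names(relation_mix)),
            n_docs >= 0L, relations_per_doc >= 0L, filler_sentences >= 0L,
            negative_density >= 0,
            all(c(POSITIVE_RELATIONS, "Neg") %in% names(cue_words)),
            !anyDuplicated(cue_words))
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 vocab_sizes = vocab_sizes, relation_mix = relation_mix,
                 relations_per_doc = as.integer(relations_per_doc),
                 filler_sentences = as.integer(filler_sentences),
                 negative_density = negative_density, cue_words = cue_words),
            class = "generator_spec")
}

# deterministic entity pools: id, type, display name (herbs are two-word
# binomial-style names so that multiword surface forms are exercised)
entity_pools <- function(vocab_sizes) {
  pools <- list(
    Herb = data.frame(
      entity_id = sprintf("H%04d", seq_len(vocab_sizes[["Herb"]])),
      etype = "Herb",
      text = sprintf("Herbora folium%d", seq_len(vocab_sizes[["Herb"]])),
      stringsAsFactors = FALSE),
    Chemical = data.frame(
      entity_id = sprintf("C%04d", seq_len(vocab_sizes[["Chemical"]])),
      etype = "Chemical",
      text = sprintf("chemicin%d", seq_len(vocab_sizes[["Chemical"]])),
      stringsAsFactors = FALSE),
    Disease = data.frame(
      entity_id = sprintf("D%04d", seq_len(vocab_sizes[["Disease"]])),
      etype = "Disease",
      text = sprintf("morbus%d", seq_len(vocab_sizes[["Disease"]])),
      stringsAsFactors = FALSE),
    Gene = data.frame(
      entity_id = sprintf("G%04d", seq_len(vocab_sizes[["Gene"]])),
      etype = "Gene",
      text = sprintf("GENX%d", seq_len(vocab_sizes[["Gene"]])),
      stringsAsFactors = FALSE))
  pools
}

FILLER_WORDS <- c("baseline", "cohort", "assay", "signal", "profile",
                  "stable", "marked", "observed", "tissue", "culture",
                  "dose", "response", "control", "sample", "panel")

# a document is composed from segments; entity segments become mentions with
# exact offsets into title + " " + abstract
doc_composer <- function(pmid) {
  env <- new.env(parent = emptyenv())
  env$pieces <- character()
  env$mentions <- list()
  env$offset <- 0L
  env$add <- function(txt, ent = NULL) {
    if (!is.null(ent)) {
      env$mentions[[length(env$mentions) + 1L]] <- data.frame(
        pmid = pmid, start = env$offset, end = env$offset + nchar(txt),
        text = txt, etype = ent$etype, entity_id = ent$entity_id,
        stringsAsFactors = FALSE)
    }
    env$pieces <- c(env$pieces, txt)
    env$offset <- env$offset + nchar(txt)
  }
  env
}

#' Generate a synthetic annotated corpus
#'
#' Each document carries a synthetic title and abstract assembled from
#' relation-bearing sentences (`"<head> <cue> <tail> in <filler> assays."`),
#' unrelated co-mention sentences and filler sentences; all entity
#' occurrences get exact gold mentions and every planted relation a gold
#' relation annotation. The ground-truth graph is the union of planted
#' relations.
#'
#' @param spec a [generator_spec()].
#' @return list with `docs` (list of `annotated_document`) and `truth`
#'   (list with `entities` and `relations` data.frames).
#' @export
generate_corpus <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  pools <- entity_pools(spec$vocab_sizes)
  mix <- spec$relation_mix[POSITIVE_RELATIONS] / sum(spec$relation_mix)
  with_seed(spec$seed, {
    docs <- vector("list", spec$n_docs)
    truth_rel <- list()
    for (d in seq_len(spec$n_docs)) {
      pmid <- sprintf("%d", 1000000L + d)
      n_rel <- spec$relations_per_doc
      rtypes <- sample(POSITIVE_RELATIONS, n_rel, replace = TRUE, prob = mix)
      planted <- list()
      seen <- character()
      for (rt in rtypes) {
        sig <- SIGNATURES[[rt]]
        repeat {
          h <- pools[[sig[1L]]][sample.int(nrow(pools[[sig[1L]]]), 1L), ]
          t <- pools[[sig[2L]]][sample.int(nrow(pools[[sig[2L]]]), 1L), ]
          key <- paste(rt, h$entity_id, t$entity_id)
          if (h$entity_id != t$entity_id && !key %in% seen) break
        }
        seen <- c(seen, key)
        planted[[length(planted) + 1L]] <- list(rtype = rt, head = h, tail = t)
      }
      n_neg <- rbinom(1L, 4L, min(1, spec$negative_density / 4))
      negs <- list()
      for (k in seq_len(n_neg)) {
        rt <- sample(POSITIVE_RELATIONS, 1L)
        sig <- SIGNATURES[[rt]]
        h <- pools[[sig[1L]]][sample.int(nrow(pools[[sig[1L]]]), 1L), ]
        t <- pools[[sig[2L]]][sample.int(nrow(pools[[sig[2L]]]), 1L), ]
        key <- paste(rt, h$entity_id, t$entity_id)
        if (key %in% seen || h$entity_id == t$entity_id) next
        negs[[length(negs) + 1L]] <- list(head = h, tail = t)
      }
      cmp <- doc_composer(pmid)
      # title mentions the first planted head entity
      cmp$add("Assessment of ")
      cmp$add(planted[[1L]]$head$text, planted[[1L]]$head)
      cmp$add(" in a screening cohort.")
      cmp$add(" ")   # title/abstract separator
      first <- TRUE
      add_sentence <- function(head, verb, tail) {
        if (!first) cmp$add(" ")
        first <<- FALSE
        cmp$add(head$text, head)
        cmp$add(paste0(" ", verb, " "))
        cmp$add(tail$text, tail)
        cmp$add(sprintf(" in %s assays.", sample(FILLER_WORDS, 1L)))
      }
      for (p in planted) {
        add_sentence(p$head, spec$cue_words[[p$rtype]], p$tail)
      }
      for (ng in negs) {
        add_sentence(ng$head, spec$cue_words[["Neg"]], ng$tail)
      }
      for (k in seq_len(spec$filler_sentences)) {
        if (!first) cmp$add(" ")
        first <- FALSE
        cmp$add(sprintf("The %s showed %s %s measures.",
                        sample(FILLER_WORDS, 1L), sample(FILLER_WORDS, 1L),
                        sample(FILLER_WORDS, 1L)))
      }
      full <- paste(cmp$pieces, collapse = "")
      title_end <- regexpr(".", full, fixed = TRUE)  # first sentence = title
      title_end <- as.integer(title_end)
      title <- substr(full, 1L, title_end)
      abstract <- substr(full, title_end + 2L, nchar(full))
      relations <- do.call(rbind, lapply(planted, function(p) data.frame(
        pmid = pmid, rtype = p$rtype, head_id = p$head$entity_id,
        tail_id = p$tail$entity_id, stringsAsFactors = FALSE)))
      relations <- relations[!duplicated(relations), , drop = FALSE]
      docs[[d]] <- annotated_document(
        pmid = pmid, title = title, abstract = abstract,
        mentions = do.call(rbind, cmp$mentions), relations = relations)
      truth_rel[[d]] <- relations
    }
    truth_rel <- do.call(rbind, truth_rel)
    truth_rel <- unique(truth_rel[, c("rtype", "head_id", "tail_id")])
    rownames(truth_rel) <- NULL
    entities <- do.call(rbind, pools)
    rownames(entities) <- NULL
    list(docs = docs,
         truth = list(entities = entities, relations = truth_rel))
  })
}

#' Generate a linearly separable relation-extraction set
#'
#' Builds labelled sentence-pair examples whose label is a deterministic
#' function of a planted cue word: each sentence A contains exactly one cue
#' word (the one mapped to its label), entity surface forms are drawn from
#' pools shared across labels, and `Neg` examples cycle through all five
#' type signatures so entity types alone cannot resolve the label. A rule
#' "predict by cue word" scores 100% on the set; a small classifier can
#' therefore be driven to perfect training accuracy, and occlusion-based
#' attribution has a known most-important token.
#'
#' @param n_per_class named integer vector of examples per label, or a
#'   single integer used for all six labels.
#' @param seed integer RNG seed.
#' @param spec a [generator_spec()] supplying entity pools and cue words.
#' @return an [re_examples()] data.frame.
#' @export
make_separable_re_set <- function(n_per_class = 10L, seed = 1L,
                                  spec = generator_spec(seed = seed)) {
  if (length(n_per_class) == 1L && is.null(names(n_per_class))) {
    n_per_class <- stats::setNames(rep(as.integer(n_per_class), 6L),
                                   ALL_RELATIONS)
  }
  stopifnot(all(ALL_RELATIONS %in% names(n_per_class)))
  pools <- entity_pools(spec$vocab_sizes)
  with_seed(seed, {
    rows <- list()
    for (lab in ALL_RELATIONS) {
      for (k in seq_len(n_per_class[[lab]])) {
        sig_lab <- if (lab == "Neg") {
          POSITIVE_RELATIONS[1L + (k - 1L) %% 5L]   # cycle signatures
        } else lab
        sig <- SIGNATURES[[sig_lab]]
        h <- pools[[sig[1L]]][sample.int(nrow(pools[[sig[1L]]]), 1L), ]
        t <- pools[[sig[2L]]][sample.int(nrow(pools[[sig[2L]]]), 1L), ]
        cue <- spec$cue_words[[lab]]
        sa <- sprintf("%s %s %s in %s assays.", h$text, cue, t$text,
                      sample(FILLER_WORDS, 1L))
        rows[[length(rows) + 1L]] <- data.frame(
          sentence_a = sa, head_text = h$text, tail_text = t$text,
          label = lab, pmid = sprintf("syn%05d", length(rows) + 1L),
          head_id = h$entity_id, tail_id = t$entity_id,
          origin = if (lab == "Neg") "sampled_negative" else "annotated",
          stringsAsFactors = FALSE)
      }
    }
    re_examples(do.call(rbind, rows))
  })
}
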
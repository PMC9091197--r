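placeholder <- function(etype) paste0("[", etype, "]")
PLACEHOLDER_RE <- "\\[(Herb|Chemical|Disease|Gene)\\]"

# placeholder occurrences in a template text: data.frame(start, end, etype)
find_placeholders <- function(text) {
  m <- gregexpr(PLACEHOLDER_RE, text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      etype = character(), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + len - 1L,
             etype = substr(substring(text, m, m + len - 1L), 2L,
                            len - 1L),
             stringsAsFactors = FALSE)
}

#' Extract a template corpus for one relation type (Substitution I)
#'
#' Scans every sentence of every document; a sentence qualifies when it
#' contains mentions of both endpoints of some relation of the requested
#' type. Every entity mention inside a qualifying sentence — of any type —
#' is replaced by its type placeholder (`[Herb]`, `[Chemical]`, `[Disease]`,
#' `[Gene]`), so a generator can learn the semantic frame between generic
#' entity types rather than particular mentions. One corpus per relation
#' type; duplicated template texts are collapsed.
#'
#' @param docs list of adapted, annotated `annotated_document` objects.
#' @param rtype one of the five positive relation labels.
#' @param sep title/abstract separator.
#' @return data.frame of class `template_corpus` with columns `text`,
#'   `rtype`, `source` (pmid or `"generated"`).
#' @export
extract_template_corpus <- function(docs, rtype, sep = " ") {
  stopifnot(rtype %in% POSITIVE_RELATIONS)
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  out <- list()
  for (doc in docs) {
    rels <- doc$relations[doc$relations$rtype == rtype, , drop = FALSE]
    if (!nrow(rels)) next
    text <- doc_text(doc, sep = sep)
    sents <- split_sentences(text)
    m <- doc$mentions
    for (s in seq_len(nrow(sents))) {
      lo <- sents$start[s]; hi <- sents$end[s]
      inside <- which(m$start >= lo & m$end <= hi)
      if (!length(inside)) next
      ids_in <- m$entity_id[inside]
      hit <- any(rels$head_id %in% ids_in & rels$tail_id %in% ids_in)
      if (!hit) next
      sent <- sents$sentence[s]
      ord <- inside[order(m$start[inside], decreasing = TRUE)]
      for (i in ord) {    # replace right-to-left so offsets stay valid
        a <- m$start[i] - lo
        b <- m$end[i] - lo
        sent <- paste0(substr(sent, 1L, a), placeholder(m$etype[i]),
                       substring(sent, b + 1L))
      }
      out[[length(out) + 1L]] <- data.frame(text = sent, rtype = rtype,
                                            source = doc$pmid,
                                            stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(text = character(), rtype = character(),
               source = character(), stringsAsFactors = FALSE)
  }
  res <- res[!duplicated(res$text), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("template_corpus", "data.frame")
  res
}

# split a template with exactly one head- and one tail-type placeholder into
# prefix / middle / suffix fragments, recording the placeholder order
template_fragments <- function(text, head_type, tail_type) {
  ph <- find_placeholders(text)
  if (sum(ph$etype == head_type) != 1L || sum(ph$etype == tail_type) != 1L ||
      nrow(ph) != 2L) {
    return(NULL)
  }
  ph <- ph[order(ph$start), , drop = FALSE]
  list(prefix = substr(text, 1L, ph$start[1L] - 1L),
       middle = substr(text, ph$end[1L] + 1L, ph$start[2L] - 1L),
       suffix = substring(text, ph$end[2L] + 1L),
       types = ph$etype)
}

#' Generate new templates from a template corpus
#'
#' The template generator is a pluggable contract: it must return `n`
#' templates for the corpus's relation type, each containing exactly one
#' head-type and one tail-type placeholder. The default desk-scale generator
#' splits each corpus template at its two placeholders and recombines
#' prefix, middle and suffix fragments across templates (seeded); a
#' generative language-model backend can be substituted behind the same
#' contract. Corpus templates carrying extra placeholders are normalized by
#' spelling extra occurrences out as lowercase type words before
#' fragmenting.
#'
#' @param corpus a [extract_template_corpus()] result (single relation
#'   type, non-empty).
#' @param n number of templates to generate.
#' @param seed integer RNG seed.
#' @return data.frame of generated templates (`source = "generated"`).
#' @export
generate_templates <- function(corpus, n, seed = 1L) {
  if (!nrow(corpus)) stop("template corpus is empty")
  rtype <- unique(corpus$rtype)
  stopifnot(length(rtype) == 1L)
  sig <- SIGNATURES[[rtype]]
  norm_text <- vapply(corpus$text, function(tx) {
    # keep first head-type and first tail-type placeholder, demote the rest
    ph <- find_placeholders(tx)
    keep <- c(which(ph$etype == sig[1L])[1L], which(ph$etype == sig[2L])[1L])
    drop <- setdiff(seq_len(nrow(ph)), keep)
    for (i in rev(drop)) {
      tx <- paste0(substr(tx, 1L, ph$start[i] - 1L), tolower(ph$etype[i]),
                   substring(tx, ph$end[i] + 1L))
    }
    tx
  }, "", USE.NAMES = FALSE)
  frags <- Filter(Negate(is.null),
                  lapply(norm_text, template_fragments,
                         head_type = sig[1L], tail_type = sig[2L]))
  if (!length(frags)) stop("no usable two-placeholder templates in corpus")
  if (n == 0L) {
    return(data.frame(text = character(), rtype = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    texts <- vapply(seq_len(n), function(k) {
      a <- frags[[sample.int(length(frags), 1L)]]
      b <- frags[[sample.int(length(frags), 1L)]]
      c3 <- frags[[sample.int(length(frags), 1L)]]
      paste0(a$prefix, placeholder(a$types[1L]), b$middle,
             placeholder(a$types[2L]), c3$suffix)
    }, "")
    data.frame(text = texts, rtype = rtype, source = "generated",
               stringsAsFactors = FALSE)
  })
}

#' Entity database for template realization
#'
#' Per-type entity surface forms plus known related pairs per positive
#' relation type; every pair's endpoints must be listed entities of the
#' types the relation's signature requires, which is what guarantees label
#' soundness of augmented examples.
#'
#' @param entities data.frame with columns `etype`, `text`.
#' @param pairs data.frame with columns `rtype`, `head_text`, `tail_text`.
#' @return object of class `entity_db`.
#' @export
entity_db <- function(entities, pairs) {
  entities <- unique(as.data.frame(entities,
                                   stringsAsFactors = FALSE)[, c("etype", "text")])
  pairs <- unique(as.data.frame(pairs,
                                stringsAsFactors = FALSE)[, c("rtype", "head_text",
                                                              "tail_text")])
  stopifnot(all(entities$etype %in% entity_types()),
            all(pairs$rtype %in% POSITIVE_RELATIONS))
  for (i in seq_len(nrow(pairs))) {
    sig <- SIGNATURES[[pairs$rtype[i]]]
    ok_h <- pairs$head_text[i] %in% entities$text[entities$etype == sig[1L]]
    ok_t <- pairs$tail_text[i] %in% entities$text[entities$etype == sig[2L]]
    if (!ok_h || !ok_t) {
      stop(sprintf("pair %s(%s, %s) does not match its type signature",
                   pairs$rtype[i], pairs$head_text[i], pairs$tail_text[i]))
    }
  }
  structure(list(entities = entities, pairs = pairs), class = "entity_db")
}

#' @export
print.entity_db <- function(x, ...) {
  cat(sprintf("<entity_db: %d entity(ies), %d known pair(s)>\n",
              nrow(x$entities), nrow(x$pairs)))
  invisible(x)
}

#' @rdname entity_db
#' @param docs list of `annotated_document` objects whose mentions and
#'   relation annotations populate the database.
#' @export
entity_db_from_docs <- function(docs) {
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  ents <- list(); prs <- list()
  for (doc in docs) {
    de <- doc_entities(doc)
    ents[[length(ents) + 1L]] <- data.frame(etype = de$etype, text = de$text,
                                            stringsAsFactors = FALSE)
    r <- doc$relations
    for (i in seq_len(nrow(r))) {
      ht <- de$text[match(r$head_id[i], de$entity_id)]
      tt <- de$text[match(r$tail_id[i], de$entity_id)]
      if (is.na(ht) || is.na(tt)) next
      prs[[length(prs) + 1L]] <- data.frame(rtype = r$rtype[i],
                                            head_text = ht, tail_text = tt,
                                            stringsAsFactors = FALSE)
    }
  }
  entity_db(do.call(rbind, ents), do.call(rbind, prs))
}

#' @rdname entity_db
#' @param entities_path,pairs_path TSV files: entities as
#'   `type<TAB>surface form`, pairs as `rtype<TAB>head<TAB>tail`.
#' @export
read_entity_db <- function(entities_path, pairs_path) {
  e <- utils::read.delim(entities_path, header = FALSE,
                         col.names = c("etype", "text"),
                         stringsAsFactors = FALSE)
  p <- utils::read.delim(pairs_path, header = FALSE,
                         col.names = c("rtype", "head_text", "tail_text"),
                         stringsAsFactors = FALSE)
  entity_db(e, p)
}

#' Realize templates with known related entity pairs (Substitution II)
#'
#' Each template's head-type and tail-type placeholders are replaced by a
#' known related pair of its relation type sampled from the entity database
#' (all head-type occurrences receive the head entity, all tail-type
#' occurrences the tail entity; placeholders of other types receive a
#' sampled entity of that type). The realized sentence is labelled with the
#' template's relation type, which is correct by construction because the
#' pair is a known relation of that type.
#'
#' @param templates data.frame from [generate_templates()] or
#'   [extract_template_corpus()].
#' @param db an [entity_db()] with at least one pair per template relation
#'   type (templates with no known pair are skipped with a message).
#' @param seed integer RNG seed.
#' @return an [re_examples()] data.frame with `origin = "augmented"`.
#' @export
substitution_two <- function(templates, db, seed = 1L) {
  stopifnot(inherits(db, "entity_db"))
  with_seed(seed, {
    rows <- list()
    skipped <- 0L
    for (i in seq_len(nrow(templates))) {
      rt <- templates$rtype[i]
      sig <- SIGNATURES[[rt]]
      cand <- db$pairs[db$pairs$rtype == rt, , drop = FALSE]
      if (!nrow(cand)) { skipped <- skipped + 1L; next }
      pick <- cand[sample.int(nrow(cand), 1L), ]
      tx <- templates$text[i]
      repeat {
        ph <- find_placeholders(tx)
        if (!nrow(ph)) break
        j <- nrow(ph)     # realize right-to-left
        rep_txt <- if (ph$etype[j] == sig[1L]) pick$head_text
                   else if (ph$etype[j] == sig[2L]) pick$tail_text
                   else {
                     pool <- db$entities$text[db$entities$etype == ph$etype[j]]
                     if (length(pool)) sample_exact(pool, 1L) else
                       tolower(ph$etype[j])
                   }
        tx <- paste0(substr(tx, 1L, ph$start[j] - 1L), rep_txt,
                     substring(tx, ph$end[j] + 1L))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_a = tx, head_text = pick$head_text,
        tail_text = pick$tail_text, label = rt,
        pmid = templates$source[i], head_id = NA_character_,
        tail_id = NA_character_, origin = "augmented",
        stringsAsFactors = FALSE)
    }
    if (skipped > 0L) {
      message(sprintf("substitution II: %d template(s) skipped (no known pair)",
                      skipped))
    }
    if (!length(rows)) return(build_examples(list()))
    re_examples(do.call(rbind, rows))
  })
}

#' Augment a training set with realized synthetic examples
#'
#' Runs the full augmentation pipeline — template-corpus extraction,
#' template generation and pair substitution — for every positive relation
#' type and appends the realized examples (origin `augmented`) to the
#' original training examples. Augmented examples belong to training only;
#' the provenance flag keeps them out of any test partition.
#'
#' @param train an [re_examples()] training set.
#' @param docs annotated documents supplying template sentences.
#' @param db an [entity_db()].
#' @param n_per_rtype templates generated per relation type (0 = no-op).
#' @param seed integer RNG seed.
#' @param sep title/abstract separator.
#' @return an [re_examples()] data.frame: `train` plus augmented rows.
#' @export
augment_training_set <- function(train, docs, db, n_per_rtype = 10L,
                                 seed = 1L, sep = " ") {
  if (n_per_rtype == 0L) return(train)
  extra <- list()
  for (k in seq_along(POSITIVE_RELATIONS)) {
    rt <- POSITIVE_RELATIONS[k]
    corpus <- extract_template_corpus(docs, rt, sep = sep)
    if (!nrow(corpus)) next
    tpl <- generate_templates(corpus, n_per_rtype, seed = seed + k)
    realized <- substitution_two(tpl, db, seed = seed + 100L + k)
    if (nrow(realized)) extra[[length(extra) + 1L]] <- realized
  }
  if (!length(extra)) return(train)
  re_examples(rbind(as.data.frame(train), do.call(rbind, extra)))
}
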
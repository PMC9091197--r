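RE_EXAMPLE_COLS <- c("sentence_a", "sentence_b", "head_text", "tail_text",
                     "label", "pmid", "head_id", "tail_id", "origin")

#' Relation-extraction examples
#'
#' A classification instance is a sentence pair: sentence A is the title and
#' abstract joined by a space, sentence B is the head entity surface form, a
#' single separator space, and the tail entity surface form. Entity surface
#' forms may themselves contain spaces, so the split point is recorded in the
#' `head_text`/`tail_text` columns. `origin` tracks provenance: `annotated`,
#' `sampled_negative` or `augmented`.
#'
#' @param df data.frame with columns `sentence_a`, `head_text`, `tail_text`,
#'   `label`, `pmid`, `head_id`, `tail_id`, `origin` (`sentence_b` is derived).
#' @return data.frame of class `re_examples`.
#' @export
re_examples <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sentence_b" %in% names(df)) {
    df$sentence_b <- paste(df$head_text, df$tail_text)
  }
  stopifnot(all(RE_EXAMPLE_COLS %in% names(df)))
  bad <- setdiff(unique(df$label), ALL_RELATIONS)
  if (length(bad)) stop("unknown relation label(s): ", paste(bad, collapse = ", "))
  df <- df[, RE_EXAMPLE_COLS, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("re_examples", "data.frame")
  df
}

#' Extract positive examples from annotated documents
#'
#' One example per relation annotation. The surface form used in sentence B
#' is the text of the first mention (by start offset) carrying the relation
#' endpoint's entity id. Relations whose endpoints resolve to no mention are
#' skipped and reported via a warning.
#'
#' @param docs list of `annotated_document` objects.
#' @param sep title/abstract separator.
#' @return an [re_examples()] data.frame with `origin = "annotated"`.
#' @export
build_examples <- function(docs, sep = " ") {
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  rows <- list()
  skipped <- character()
  for (doc in docs) {
    r <- doc$relations
    if (!nrow(r)) next
    m <- doc$mentions[order(doc$mentions$start), , drop = FALSE]
    first_text <- function(id) {
      i <- match(id, m$entity_id)
      if (is.na(i)) NA_character_ else m$text[i]
    }
    sa <- doc_text(doc, sep = sep)
    for (i in seq_len(nrow(r))) {
      ht <- first_text(r$head_id[i])
      tt <- first_text(r$tail_id[i])
      if (is.na(ht) || is.na(tt)) {
        skipped <- c(skipped, sprintf("%s %s %s->%s", doc$pmid, r$rtype[i],
                                      r$head_id[i], r$tail_id[i]))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_a = sa, head_text = ht, tail_text = tt, label = r$rtype[i],
        pmid = doc$pmid, head_id = r$head_id[i], tail_id = r$tail_id[i],
        origin = "annotated", stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning(sprintf("skipped %d relation(s) with unresolvable endpoints: %s",
                    length(skipped), paste(head(skipped, 5L), collapse = "; ")))
  }
  if (!length(rows)) {
    return(re_examples(data.frame(sentence_a = character(),
                                  head_text = character(),
                                  tail_text = character(),
                                  label = character(), pmid = character(),
                                  head_id = character(),
                                  tail_id = character(),
                                  origin = character(),
                                  stringsAsFactors = FALSE)))
  }
  re_examples(do.call(rbind, rows))
}

# distinct entities of a document: first mention per entity id
doc_entities <- function(doc) {
  m <- doc$mentions[order(doc$mentions$start), , drop = FALSE]
  m[!duplicated(m$entity_id), c("entity_id", "etype", "text"), drop = FALSE]
}

# ordered entity-id pairs of a document whose types fit a positive signature
# and which carry no relation annotation
eligible_negative_pairs <- function(doc) {
  ents <- doc_entities(doc)
  out <- list()
  annotated <- paste(doc$relations$head_id, doc$relations$tail_id)
  for (i in seq_len(nrow(ents))) {
    for (j in seq_len(nrow(ents))) {
      if (i == j) next
      pair_types <- c(ents$etype[i], ents$etype[j])
      fits <- any(vapply(SIGNATURES, identical, TRUE, y = pair_types))
      if (!fits) next
      if (paste(ents$entity_id[i], ents$entity_id[j]) %in% annotated) next
      out[[length(out) + 1L]] <- data.frame(
        head_id = ents$entity_id[i], tail_id = ents$entity_id[j],
        head_text = ents$text[i], tail_text = ents$text[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(head_id = character(), tail_id = character(),
                      head_text = character(), tail_text = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Sample negative examples
#'
#' Negatives are ordered within-document mention pairs whose entity types fit
#' some positive relation signature but which carry no relation annotation;
#' they receive the pseudo-label `Neg`. Sampling is without replacement and
#' deterministic given `seed`; documents with fewer eligible pairs than
#' requested contribute all their pairs (the shortfall is messaged).
#'
#' @param docs list of `annotated_document` objects.
#' @param n_per_doc maximum negatives drawn per document.
#' @param seed integer RNG seed.
#' @param sep title/abstract separator.
#' @return an [re_examples()] data.frame with `origin = "sampled_negative"`.
#' @export
sample_negatives <- function(docs, n_per_doc, seed = 1L, sep = " ") {
  stopifnot(n_per_doc >= 0)
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  with_seed(seed, {
    rows <- list()
    shortfall <- 0L
    for (doc in docs) {
      elig <- eligible_negative_pairs(doc)
      k <- min(n_per_doc, nrow(elig))
      if (k < n_per_doc) shortfall <- shortfall + (n_per_doc - k)
      if (k == 0L) next
      take <- elig[sort(sample.int(nrow(elig), k)), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_a = doc_text(doc, sep = sep),
        head_text = take$head_text, tail_text = take$tail_text,
        label = "Neg", pmid = doc$pmid, head_id = take$head_id,
        tail_id = take$tail_id, origin = "sampled_negative",
        stringsAsFactors = FALSE)
    }
    if (shortfall > 0L) {
      message(sprintf("negative sampling: %d fewer pair(s) than requested",
                      shortfall))
    }
    if (!length(rows)) {
      return(build_examples(list()))   # empty frame with the right columns
    }
    re_examples(do.call(rbind, rows))
  })
}

#' Split examples into training and test sets
#'
#' A 3:1 train:test split by default. Under stratification the global test
#' size `round(n / 4)` is apportioned across labels by largest remainder on
#' each label's quarter share (ties broken in canonical label order), so each
#' label's test share stays within one example of its proportion and
#' remainders go to the training set. Labels with fewer than 4 examples go
#' entirely to training (with a warning). Deterministic given `seed`.
#'
#' @param examples an [re_examples()] data.frame.
#' @param ratio length-2 train:test proportion, default `c(3, 1)`.
#' @param seed integer RNG seed.
#' @param stratify stratify by label (default `TRUE`).
#' @return object of class `dataset_split`: list with `train`, `test`,
#'   `seed`, `ratio`.
#' @export
split_train_test <- function(examples, ratio = c(3, 1), seed = 1L,
                             stratify = TRUE) {
  stopifnot(nrow(examples) > 0L, length(ratio) == 2L, all(ratio > 0))
  frac <- ratio[2L] / sum(ratio)
  n <- nrow(examples)
  test_idx <- integer()
  with_seed(seed, {
    if (stratify) {
      labs <- intersect(ALL_RELATIONS, unique(examples$label))
      counts <- vapply(labs, function(l) sum(examples$label == l), 0L)
      small <- counts < 4L
      if (any(small)) {
        warning(sprintf("label(s) %s have < 4 examples; assigned to training",
                        paste(labs[small], collapse = ", ")))
      }
      labs <- labs[!small]
      counts <- counts[!small]
      if (length(labs)) {
        quota <- counts * frac
        base <- floor(quota)
        target <- round_half_up(sum(counts) * frac, 0)
        extra <- as.integer(target) - as.integer(sum(base))
        take <- base
        if (extra > 0L) {
          ord <- order(-(quota - base), match(labs, ALL_RELATIONS))
          take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
        }
        for (k in seq_along(labs)) {
          rows <- which(examples$label == labs[k])
          test_idx <- c(test_idx, sample_exact(rows, take[k]))
        }
      }
    } else {
      target <- as.integer(round_half_up(n * frac, 0))
      test_idx <- sample.int(n, target)
    }
  })
  test_idx <- sort(test_idx)
  train <- examples[setdiff(seq_len(n), test_idx), , drop = FALSE]
  test <- examples[test_idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  structure(list(train = re_examples(train), test = re_examples(test),
                 seed = seed, ratio = ratio),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split %s: %d train / %d test>\n",
              paste(x$ratio, collapse = ":"), nrow(x$train), nrow(x$test)))
  invisible(x)
}

#' Per-label dataset statistics
#'
#' Counts per relation label (canonical order HHC, HTD, CAD, CAG, GID, Neg)
#' for the training/test partitions and in total, plus each label's
#' percentage of the grand total, rounded half-up to one decimal.
#'
#' @param x an [re_examples()] data.frame, a `dataset_split`, or a named
#'   integer vector of per-label total counts.
#' @return object of class `dataset_stats`: a data.frame with one column per
#'   label and rows `train`, `test`, `total`, `pct` (train/test rows are
#'   `NA` when only totals are known).
#' @export
compute_stats <- function(x) {
  count_by <- function(ex) {
    vapply(ALL_RELATIONS, function(l) sum(ex$label == l), 0L)
  }
  if (inherits(x, "dataset_split")) {
    tr <- count_by(x$train); te <- count_by(x$test)
    tot <- tr + te
  } else if (is.data.frame(x)) {
    tr <- te <- rep(NA_integer_, length(ALL_RELATIONS))
    tot <- count_by(x)
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)))
    tr <- te <- rep(NA_integer_, length(ALL_RELATIONS))
    tot <- vapply(ALL_RELATIONS, function(l) {
      if (l %in% names(x)) as.integer(x[[l]]) else 0L
    }, 0L)
  }
  stopifnot(all(tot >= 0L, na.rm = TRUE))
  pct <- round_half_up(100 * tot / sum(tot), 1)
  out <- rbind(train = tr, test = te, total = tot, pct = pct)
  colnames(out) <- ALL_RELATIONS
  structure(as.data.frame(out), class = c("dataset_stats", "data.frame"))
}

#' Read and write relation-extraction TSV files
#'
#' The exchange format is three tab-separated columns per line: sentence A,
#' sentence B, label — no header. [write_re_jsonl()] keeps full provenance
#' (one JSON object per line).
#'
#' @param examples an [re_examples()] data.frame.
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_re_tsv` returns an
#'   [re_examples()] data.frame (provenance fields empty, sentence B split at
#'   the first space).
#' @export
write_re_tsv <- function(examples, path) {
  lines <- paste(examples$sentence_a, examples$sentence_b, examples$label,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_re_tsv
#' @export
read_re_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop(sprintf("line %d: expected 3 tab-separated fields",
                                bad[1L]))
  sa <- vapply(parts, `[`, "", 1L)
  sb <- vapply(parts, `[`, "", 2L)
  lab <- vapply(parts, `[`, "", 3L)
  ht <- sub(" .*$", "", sb)
  tt <- sub("^[^ ]* ", "", sb)
  re_examples(data.frame(sentence_a = sa, sentence_b = sb, head_text = ht,
                         tail_text = tt, label = lab, pmid = NA_character_,
                         head_id = NA_character_, tail_id = NA_character_,
                         origin = "annotated", stringsAsFactors = FALSE))
}

#' @rdname write_re_tsv
#' @export
write_re_jsonl <- function(examples, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(examples))) {
    writeLines(jsonlite::toJSON(as.list(examples[i, , drop = FALSE]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
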
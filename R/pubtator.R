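POSITIVE_RELATIONS <- c("HHC", "HTD", "CAD", "CAG", "GID")
ALL_RELATIONS <- c(POSITIVE_RELATIONS, "Neg")

empty_mentions <- function() {
  data.frame(pmid = character(), start = integer(), end = integer(),
             text = character(), etype = character(),
             entity_id = character(), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(pmid = character(), rtype = character(),
             head_id = character(), tail_id = character(),
             stringsAsFactors = FALSE)
}

#' Construct an annotated document
#'
#' An annotated document is one abstract in the PubTator annotation exchange
#' format: a title, an abstract body, typed entity mentions with character
#' offsets, and relation annotations between entity identifiers. Offsets are
#' 0-based and end-exclusive, and index the concatenation
#' `title + sep + abstract` (see [doc_text()]).
#'
#' @param pmid document identifier (coerced to character).
#' @param title title text.
#' @param abstract abstract text.
#' @param mentions data.frame with columns `pmid`, `start`, `end`, `text`,
#'   `etype`, `entity_id` (defaults to none).
#' @param relations data.frame with columns `pmid`, `rtype`, `head_id`,
#'   `tail_id` (defaults to none).
#' @return an object of class `annotated_document`.
#' @seealso [parse_pubtator()], [validate_document()]
#' @export
annotated_document <- function(pmid, title, abstract,
                               mentions = empty_mentions(),
                               relations = empty_relations()) {
  stopifnot(length(pmid) == 1L, length(title) == 1L, length(abstract) == 1L)
  mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  need_m <- c("pmid", "start", "end", "text", "etype", "entity_id")
  need_r <- c("pmid", "rtype", "head_id", "tail_id")
  stopifnot(all(need_m %in% names(mentions)), all(need_r %in% names(relations)))
  mentions$pmid <- as.character(mentions$pmid)
  mentions$start <- as.integer(mentions$start)
  mentions$end <- as.integer(mentions$end)
  mentions$entity_id <- as.character(mentions$entity_id)
  relations$pmid <- as.character(relations$pmid)
  relations$head_id <- as.character(relations$head_id)
  relations$tail_id <- as.character(relations$tail_id)
  structure(list(pmid = as.character(pmid), title = title,
                 abstract = abstract,
                 mentions = mentions[, need_m, drop = FALSE],
                 relations = relations[, need_r, drop = FALSE]),
            class = "annotated_document")
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document %s: %d mention(s), %d relation(s)>\n",
              x$pmid, nrow(x$mentions), nrow(x$relations)))
  cat("  ", substr(x$title, 1, 70), "\n", sep = "")
  invisible(x)
}

#' Concatenated document text
#'
#' Mention offsets index the title and abstract joined by a single separator
#' (a space by default); title offsets start at 0 and abstract offsets
#' continue past the title.
#'
#' @param doc an `annotated_document`.
#' @param sep separator between title and abstract.
#' @return character scalar.
#' @export
doc_text <- function(doc, sep = " ") {
  paste(doc$title, doc$abstract, sep = sep)
}

split_dialect <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) >= 2L) return(f)
  strsplit(line, "|", fixed = TRUE)[[1]]
}

#' Parse PubTator-format text
#'
#' Reads blocks separated by blank lines. Within a block: a title line and an
#' abstract line (either `pmid<TAB>text`, or the pipe dialect `pmid|t|text` /
#' `pmid|a|text`), zero or more 6-field entity-mention lines
#' (`pmid, start, end, text, type, entity id`) and zero or more 4-field
#' relation lines (`pmid, relation type, head id, tail id`). Section order
#' within a block does not affect the result; offsets are preserved verbatim.
#'
#' @param lines character vector of lines (e.g. from [readLines()]).
#' @return list of [annotated_document()] objects.
#' @export
parse_pubtator <- function(lines) {
  stopifnot(is.character(lines))
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, diff(!blank) == 1L) & !blank)
  docs <- list()
  idx <- seq_along(lines)
  for (g in unique(grp[!blank])) {
    sel <- idx[grp == g & !blank]
    docs[[length(docs) + 1L]] <- parse_block(lines[sel], sel)
  }
  docs
}

parse_block <- function(block, lineno) {
  pmid <- NULL
  title <- NA_character_
  abstract <- ""
  have_title <- FALSE
  have_abstract <- FALSE
  mention_rows <- list()
  relation_rows <- list()
  for (i in seq_along(block)) {
    f <- split_dialect(block[[i]])
    n <- length(f)
    if (n == 3L && f[2L] %in% c("t", "a")) {       # pipe dialect text line
      if (f[2L] == "t") { title <- f[3L]; have_title <- TRUE }
      else { abstract <- f[3L]; have_abstract <- TRUE }
      pmid <- pmid %||% f[1L]
    } else if (n == 2L) {                          # tab dialect text line
      if (!have_title) { title <- f[2L]; have_title <- TRUE }
      else if (!have_abstract) { abstract <- f[2L]; have_abstract <- TRUE }
      else stop(sprintf("line %d: third plain-text line in block", lineno[i]))
      pmid <- pmid %||% f[1L]
    } else if (n == 6L) {                          # mention line
      if (grepl("\\D", f[2L]) || grepl("\\D", f[3L])) {
        stop(sprintf("line %d: non-integer mention offsets '%s'/'%s'",
                     lineno[i], f[2L], f[3L]))
      }
      mention_rows[[length(mention_rows) + 1L]] <- data.frame(
        pmid = f[1L], start = as.integer(f[2L]), end = as.integer(f[3L]),
        text = f[4L], etype = f[5L], entity_id = f[6L],
        stringsAsFactors = FALSE)
      pmid <- pmid %||% f[1L]
    } else if (n == 4L) {                          # relation line
      relation_rows[[length(relation_rows) + 1L]] <- data.frame(
        pmid = f[1L], rtype = f[2L], head_id = f[3L], tail_id = f[4L],
        stringsAsFactors = FALSE)
      pmid <- pmid %||% f[1L]
    } else {
      stop(sprintf("line %d: malformed line with %d field(s)", lineno[i], n))
    }
  }
  if (!have_title) stop(sprintf("line %d: block has no title line", lineno[1L]))
  annotated_document(
    pmid = pmid, title = title, abstract = abstract,
    mentions = if (length(mention_rows)) do.call(rbind, mention_rows)
               else empty_mentions(),
    relations = if (length(relation_rows)) do.call(rbind, relation_rows)
                else empty_relations())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a PubTator file
#'
#' @param path file path (UTF-8).
#' @return list of `annotated_document` objects.
#' @export
read_pubtator <- function(path) {
  parse_pubtator(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Serialize documents to PubTator format
#'
#' Sections are emitted in the order title, abstract, mentions, relations,
#' tab-delimited, with one blank line between documents. Writing refuses
#' documents whose mention offsets do not slice to the mention text
#' (relations whose endpoints are missing from the mention list are written
#' as-is: the format is lossy in published excerpts and I/O stays lossless).
#'
#' @param docs list of `annotated_document` objects (or a single one).
#' @param path optional file to write to.
#' @param validate check mention-offset invariants first (default `TRUE`).
#' @param sep title/abstract separator assumed by the offsets.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_pubtator <- function(docs, path = NULL, validate = TRUE, sep = " ") {
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  out <- character()
  for (doc in docs) {
    if (validate) {
      v <- validate_document(doc, sep = sep)
      v <- v[v$kind %in% c("slice_mismatch", "empty_span", "out_of_range"), ,
             drop = FALSE]
      if (nrow(v)) {
        stop(sprintf("document %s: refusing to write, %s (%s)",
                     doc$pmid, v$kind[1L], v$detail[1L]))
      }
    }
    lines <- c(paste(doc$pmid, doc$title, sep = "\t"),
               paste(doc$pmid, doc$abstract, sep = "\t"))
    if (nrow(doc$mentions)) {
      m <- doc$mentions
      lines <- c(lines, paste(m$pmid, m$start, m$end, m$text, m$etype,
                              m$entity_id, sep = "\t"))
    }
    if (nrow(doc$relations)) {
      r <- doc$relations
      lines <- c(lines, paste(r$pmid, r$rtype, r$head_id, r$tail_id,
                              sep = "\t"))
    }
    out <- c(out, lines, "")
  }
  if (length(out)) out <- out[-length(out)]   # no trailing blank line
  if (!is.null(path)) {
    writeLines(out, path, useBytes = FALSE)
    return(invisible(out))
  }
  out
}

#' Validate an annotated document
#'
#' Violations are data, not exceptions: every problem found is one row of the
#' returned report. Checked: mention/relation pmid agreement; offset sanity
#' (`0 <= start < end <= nchar(text)`); the slice invariant
#' `substr(text, start, end) == mention text`; relation labels drawn from the
#' five positive ontology labels; relation endpoints resolving to some
#' mention's entity id (unresolved endpoints are reported, never dropped).
#'
#' @param doc an `annotated_document`.
#' @param sep title/abstract separator assumed by the offsets.
#' @return data.frame with columns `kind`, `where`, `detail`; zero rows iff
#'   the document is internally consistent.
#' @export
validate_document <- function(doc, sep = " ") {
  text <- doc_text(doc, sep = sep)
  n <- nchar(text)
  bad <- list()
  add <- function(kind, where, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(kind = kind, where = where,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  m <- doc$mentions
  for (i in seq_len(nrow(m))) {
    tag <- sprintf("mention %d (%s)", i, m$text[i])
    if (m$pmid[i] != doc$pmid) add("pmid_mismatch", tag, m$pmid[i])
    if (is.na(m$start[i]) || is.na(m$end[i])) { add("bad_offset", tag, "NA"); next }
    if (m$start[i] == m$end[i]) { add("empty_span", tag, as.character(m$start[i])); next }
    if (m$start[i] < 0L || m$start[i] > m$end[i] || m$end[i] > n) {
      add("out_of_range", tag, sprintf("[%d,%d) in text of length %d",
                                       m$start[i], m$end[i], n))
      next
    }
    slice <- substring(text, m$start[i] + 1L, m$end[i])
    if (!identical(slice, m$text[i])) {
      add("slice_mismatch", tag, sprintf("offsets give '%s'", slice))
    }
  }
  r <- doc$relations
  ids <- unique(m$entity_id)
  for (i in seq_len(nrow(r))) {
    tag <- sprintf("relation %d (%s %s->%s)", i, r$rtype[i], r$head_id[i],
                   r$tail_id[i])
    if (r$pmid[i] != doc$pmid) add("pmid_mismatch", tag, r$pmid[i])
    if (!r$rtype[i] %in% POSITIVE_RELATIONS) {
      add("bad_relation_type", tag, r$rtype[i])
    }
    if (!r$head_id[i] %in% ids) add("unresolved_endpoint", tag, r$head_id[i])
    if (!r$tail_id[i] %in% ids) add("unresolved_endpoint", tag, r$tail_id[i])
  }
  if (!length(bad)) {
    return(data.frame(kind = character(), where = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}
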
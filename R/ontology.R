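#' The herb ontology
#'
#' Four entity types (Herb, Chemical, Disease, Gene) and five typed positive
#' relation labels, plus the pseudo-label `Neg` used for non-relations in the
#' six-class relation-extraction task:
#'
#' * `HHC` HerbHasCompoundChemical: (Herb, Chemical)
#' * `HTD` HerbTreatsDisease: (Herb, Disease)
#' * `CAD` ChemicalActsOnDisease: (Chemical, Disease)
#' * `CAG` ChemicalAssociatesGene: (Chemical, Gene)
#' * `GID` GeneInfluencesDisease: (Gene, Disease)
#'
#' @return `entity_types()`: the four entity type names.
#'   `relation_types()`: the six relation labels (`Neg` last).
#' @export
entity_types <- function() c("Herb", "Chemical", "Disease", "Gene")

#' @rdname entity_types
#' @export
relation_types <- function() ALL_RELATIONS

SIGNATURES <- list(
  HHC = c("Herb", "Chemical"),
  HTD = c("Herb", "Disease"),
  CAD = c("Chemical", "Disease"),
  CAG = c("Chemical", "Gene"),
  GID = c("Gene", "Disease")
)

#' Typed signature of a relation label
#'
#' @param rtype one of `HHC`, `HTD`, `CAD`, `CAG`, `GID`, `Neg`.
#' @return a `(head type, tail type)` character pair, or the string `"any"`
#'   for `Neg` (negatives carry no type constraint).
#' @export
relation_signature <- function(rtype) {
  stopifnot(length(rtype) == 1L)
  if (identical(rtype, "Neg")) return("any")
  sig <- SIGNATURES[[rtype]]
  if (is.null(sig)) stop(sprintf("unknown relation label '%s'", rtype))
  sig
}

#' Check a triplet against the ontology
#'
#' Only triplets whose head/tail entity types match the relation label's
#' signature may enter the knowledge graph. Mentions must carry adapted
#' (post-remap) types; `Neg` validates any pair.
#'
#' @param head_etype,tail_etype entity types of head and tail.
#' @param rtype relation label.
#' @return logical scalar.
#' @export
is_valid_triplet <- function(head_etype, tail_etype, rtype) {
  sig <- relation_signature(rtype)
  if (identical(sig, "any")) return(TRUE)
  identical(c(head_etype, tail_etype), sig)
}

#' Domain vocabulary of herb/chemical terms
#'
#' Terms are normalized to lowercase with collapsed internal whitespace.
#' Matching (see [screen_abstract()]) is case-insensitive whole-phrase
#' matching on word boundaries, so "rice" never matches inside "price".
#'
#' @param terms character vector of phrases.
#' @param types optional parallel vector (`"herb"` or `"chemical"`); untyped
#'   terms match either role.
#' @return object of class `domain_vocabulary`.
#' @export
domain_vocabulary <- function(terms, types = NULL) {
  norm <- normalize_term(terms)
  keep <- nzchar(norm)
  if (!all(keep)) stop("empty terms are not allowed in a domain vocabulary")
  if (is.null(types)) types <- rep(NA_character_, length(norm))
  types <- as.character(types)
  stopifnot(length(types) == length(norm))
  dup <- duplicated(norm)
  structure(list(terms = norm[!dup], types = types[!dup]),
            class = "domain_vocabulary")
}

#' @export
print.domain_vocabulary <- function(x, ...) {
  cat(sprintf("<domain_vocabulary: %d term(s)>\n", length(x$terms)))
  invisible(x)
}

#' @rdname domain_vocabulary
#' @param x character vector of raw phrases.
#' @export
normalize_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Read a vocabulary file
#'
#' One term per line; an optional second tab-separated column gives the term
#' type (`herb` or `chemical`).
#'
#' @param path file path.
#' @return a [domain_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(parts, `[`, "", 1L)
  types <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")
  domain_vocabulary(terms, types)
}

vocab_contains <- function(vocab, phrase) {
  normalize_term(phrase) %in% vocab$terms
}

#' Adapt raw NER annotations to the herb ontology
#'
#' Post-processing of generic biomedical NER output: `Mutation` and
#' `Cellline` mentions are removed (undefined in the ontology); a `Species`
#' mention becomes a `Herb` mention (entity id preserved) when its surface
#' text matches a vocabulary term, and is removed otherwise; `Gene`,
#' `Chemical`, `Disease` and already-adapted `Herb` mentions pass through.
#' The operation is idempotent.
#'
#' @param doc an `annotated_document` carrying raw NER tags.
#' @param vocab a [domain_vocabulary()].
#' @return the adapted `annotated_document`.
#' @export
adapt_ner_annotations <- function(doc, vocab) {
  stopifnot(inherits(vocab, "domain_vocabulary"))
  m <- doc$mentions
  if (nrow(m)) {
    drop <- m$etype %in% c("Mutation", "Cellline")
    is_species <- m$etype == "Species"
    matches <- is_species & vapply(m$text, function(t) vocab_contains(vocab, t), TRUE)
    m$etype[matches] <- "Herb"
    drop <- drop | (is_species & !matches)
    m <- m[!drop, , drop = FALSE]
    keep <- m$etype %in% entity_types()
    m <- m[keep, , drop = FALSE]
    rownames(m) <- NULL
  }
  doc$mentions <- m
  doc
}

#' Screen an abstract against the domain vocabulary
#'
#' An abstract is retained for the corpus only if its title or abstract text
#' contains at least one vocabulary phrase, matched case-insensitively as a
#' whole phrase on word boundaries.
#'
#' @param doc an `annotated_document`.
#' @param vocab a [domain_vocabulary()].
#' @param sep title/abstract separator.
#' @return logical scalar.
#' @export
screen_abstract <- function(doc, vocab, sep = " ") {
  stopifnot(inherits(vocab, "domain_vocabulary"))
  if (!length(vocab$terms)) return(FALSE)
  text <- normalize_term(doc_text(doc, sep = sep))
  for (term in vocab$terms) {
    pat <- paste0("(?<![[:alnum:]])", escape_regex(term), "(?![[:alnum:]])")
    if (grepl(pat, text, perl = TRUE)) return(TRUE)
  }
  FALSE
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
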
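PAD_TOKEN <- "[pad]"
UNK_TOKEN <- "[unk]"
SEP_TOKEN <- "[sep]"
MASK_TOKEN <- "[mask]"
OCC_TOKEN <- "[occ]"   # reserved occlusion token, never seen in training
SPECIAL_TOKENS <- c(PAD_TOKEN, UNK_TOKEN, SEP_TOKEN, MASK_TOKEN, OCC_TOKEN)

#' Whitespace tokenizer over a fixed vocabulary
#'
#' Tokens are whitespace-delimited and case-preserving, so a token sequence
#' detokenizes back to the original string exactly. The vocabulary is built
#' from a training corpus plus five reserved tokens: padding, unknown,
#' separator, mask (for masked-language-model fine-tuning) and a never
#' trained occlusion token used by token-importance attribution.
#'
#' @param texts character vector of training texts.
#' @return object of class `re_tokenizer` with elements `vocab` (character)
#'   and `index` (named integer lookup).
#' @export
build_tokenizer <- function(texts) {
  words <- sort(unique(unlist(lapply(texts, tokenize_text))))
  words <- setdiff(words, SPECIAL_TOKENS)
  vocab <- c(SPECIAL_TOKENS, words)
  structure(list(vocab = vocab,
                 index = stats::setNames(seq_along(vocab), vocab)),
            class = "re_tokenizer")
}

#' @export
print.re_tokenizer <- function(x, ...) {
  cat(sprintf("<re_tokenizer: %d token(s)>\n", length(x$vocab)))
  invisible(x)
}

#' @rdname build_tokenizer
#' @param text character scalar to split into tokens.
#' @export
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  strsplit(trimws(text), "\\s+")[[1L]]
}

encode_tokens <- function(tokenizer, tokens) {
  ids <- unname(tokenizer$index[tokens])
  ids[is.na(ids)] <- tokenizer$index[[UNK_TOKEN]]
  as.integer(ids)
}

#' Encode a sentence pair for the relation classifier
#'
#' Layout: sentence A tokens, a separator, sentence B tokens, a separator.
#' Segment ids are 1 for sentence A and its separator, 2 for sentence B and
#' its separator; position ids run 1..n. When the sequence exceeds the token
#' budget, sentence A is truncated from its tail (titles and sentence
#' openings carry the finding); sentence B is never truncated, and a
#' sentence B that cannot fit on its own is an error.
#'
#' @param sentence_a,sentence_b the two input strings (or pass an
#'   [re_examples()] row via `example`).
#' @param tokenizer an [build_tokenizer()] object.
#' @param config an [encoder_config()] supplying `max_seq_len`.
#' @param example optional one-row `re_examples` data.frame.
#' @return object of class `tokenized_pair`: list with `tokens`, `ids`,
#'   `segment`, `position`, `sep_positions`.
#' @export
tokenize_pair <- function(sentence_a = NULL, sentence_b = NULL, tokenizer,
                          config, example = NULL) {
  if (!is.null(example)) {
    sentence_a <- example$sentence_a[1L]
    sentence_b <- example$sentence_b[1L]
  }
  ta <- tokenize_text(sentence_a)
  tb <- tokenize_text(sentence_b)
  budget <- config$max_seq_len
  if (length(tb) + 2L > budget) {
    stop(sprintf("sentence B alone (%d tokens) exceeds the %d-token budget",
                 length(tb), budget))
  }
  overflow <- (length(ta) + length(tb) + 2L) - budget
  if (overflow > 0L) ta <- ta[seq_len(length(ta) - overflow)]
  tokens <- c(ta, SEP_TOKEN, tb, SEP_TOKEN)
  n <- length(tokens)
  segment <- c(rep(1L, length(ta) + 1L), rep(2L, length(tb) + 1L))
  structure(list(tokens = tokens,
                 ids = encode_tokens(tokenizer, tokens),
                 segment = segment,
                 position = seq_len(n),
                 sep_positions = c(length(ta) + 1L, n)),
            class = "tokenized_pair")
}

#' Recover sentence B from a tokenized pair
#'
#' @param pair a [tokenize_pair()] result.
#' @return character scalar: the tokens between the two separators joined by
#'   single spaces (the inverse of whitespace tokenization).
#' @export
detokenize_sentence_b <- function(pair) {
  lo <- pair$sep_positions[1L] + 1L
  hi <- pair$sep_positions[2L] - 1L
  if (hi < lo) return("")
  paste(pair$tokens[lo:hi], collapse = " ")
}
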
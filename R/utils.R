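#' Round half away from zero
#'
#' Percentage cells in relation-extraction reports are conventionally rounded
#' half-up (86.65 -> 86.7), unlike [base::round()]'s round-half-even. A small
#' epsilon guards against binary representation of exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Split text into sentences
#'
#' Rule-based segmentation: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an uppercase letter, a digit or an opening bracket.
#' Deterministic and dependency-free; abbreviations followed by an uppercase
#' word are over-split, which is acceptable for evidence extraction.
#'
#' @param text character scalar.
#' @return data.frame with columns `start`, `end` (0-based, end-exclusive
#'   offsets into `text`) and `sentence`.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer(),
                      sentence = character(), stringsAsFactors = FALSE))
  }
  # boundary = sentence-final punctuation, then whitespace, then Upper/digit/(
  bnd <- gregexpr("[.!?][\"')\\]]*\\s+(?=[A-Z0-9(\\[])", text, perl = TRUE)[[1]]
  starts <- 1L
  if (bnd[1L] != -1L) {
    lens <- attr(bnd, "match.length")
    # next sentence starts after the matched whitespace
    starts <- c(1L, as.integer(bnd) + lens)
  }
  ends <- c(starts[-1L] - 1L, nchar(text))
  out <- data.frame(start = starts - 1L, end = ends,
                    sentence = substring(text, starts, ends),
                    stringsAsFactors = FALSE)
  # trim trailing whitespace kept inside a segment (boundary ws belongs to none)
  trail <- nchar(out$sentence) - nchar(sub("\\s+$", "", out$sentence))
  out$end <- out$end - trail
  out$sentence <- sub("\\s+$", "", out$sentence)
  out[nzchar(out$sentence), , drop = FALSE]
}

# deterministic local RNG scope: evaluates expr with the given seed and
# restores the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# resample that never interprets a length-1 x as 1:x
sample_exact <- function(x, size) {
  x[sample.int(length(x), size)]
}
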
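# Published annotated sample: cinnamaldehyde immunomodulation abstract
# (pmid 9848396). Offsets are the printed ones; they index
# title + " " + abstract. The relation section references two entity ids
# (D013390, C565232) whose mentions fall in the truncated part of the
# excerpt — kept as printed, flagged by validation.
sample_cinnamaldehyde_doc <- function() {
  title <- paste("Cinnamaldehyde Inhibits Lymphocyte Proliferation and",
                 "Modulates T-Cell Differentiation.")
  abstract <- paste0(
    "Two kinds of cinnamaldehyde derivative, 2′-hydroxycinnamaldehyde ",
    "(HCA) and 2′-benzoxy-cinnamaldehyde (BCA), were studied for their ",
    "immunomodulatory effects. These compounds were screened as anticancer ",
    "drug candidates from stem bark of Cinnamomum cassia for their ",
    "inhibitory effect on farnesyl protein transferase activity.")
  mentions <- data.frame(
    pmid = "9848396",
    start = c(0L, 127L, 162L, 322L),
    end = c(14L, 151L, 187L, 339L),
    text = c("Cinnamaldehyde", "2′-hydroxycinnamaldehyde",
             "2′-benzoxy-cinnamaldehyde", "Cinnamomum cassia"),
    etype = c("Chemical", "Chemical", "Chemical", "Herb"),
    entity_id = c("C012843", "C117567", "C117567", "119260"),
    stringsAsFactors = FALSE)
  relations <- data.frame(
    pmid = "9848396",
    rtype = c("HHC", "HHC", "CAD", "CAD"),
    head_id = c("119260", "119260", "D013390", "C117567"),
    tail_id = c("D013390", "C117567", "C565232", "C565232"),
    stringsAsFactors = FALSE)
  annotated_document("9848396", title, abstract, mentions, relations)
}

# one-sentence document expressing a chemical-gene association, with
# offsets computed in code (apoptosis induction via a signalling pathway)
cag_pathway_doc <- function() {
  title <- "Cinnamaldehyde and colorectal cancer."
  abstract <- paste("Cinnamaldehyde induces apoptosis via inhibition of the",
                    "PI3K/Akt signaling pathway.")
  text <- paste(title, abstract)
  at <- function(what) {
    m <- gregexpr(what, text, fixed = TRUE)[[1L]]
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + nchar(what))
  }
  chem <- at("Cinnamaldehyde")
  gene <- at("PI3K/Akt")
  mentions <- data.frame(
    pmid = "23",
    start = c(chem$start, gene$start),
    end = c(chem$end, gene$end),
    text = c(rep("Cinnamaldehyde", nrow(chem)), rep("PI3K/Akt", nrow(gene))),
    etype = c(rep("Chemical", nrow(chem)), rep("Gene", nrow(gene))),
    entity_id = c(rep("C1", nrow(chem)), rep("G1", nrow(gene))),
    stringsAsFactors = FALSE)
  annotated_document("23", title, abstract, mentions,
                     data.frame(pmid = "23", rtype = "CAG", head_id = "C1",
                                tail_id = "G1", stringsAsFactors = FALSE))
}

# small doc builder with offsets computed from entity positions in the text
make_doc <- function(pmid, title, abstract, entities, relations = NULL) {
  text <- paste(title, abstract)
  rows <- list()
  for (i in seq_len(nrow(entities))) {
    m <- gregexpr(entities$text[i], text, fixed = TRUE)[[1L]]
    for (p in as.integer(m)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pmid = pmid, start = p - 1L, end = p - 1L + nchar(entities$text[i]),
        text = entities$text[i], etype = entities$etype[i],
        entity_id = entities$entity_id[i], stringsAsFactors = FALSE)
    }
  }
  mentions <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(pmid = character(), start = integer(), end = integer(),
               text = character(), etype = character(),
               entity_id = character(), stringsAsFactors = FALSE)
  }
  if (is.null(relations)) {
    relations <- data.frame(pmid = character(), rtype = character(),
                            head_id = character(), tail_id = character(),
                            stringsAsFactors = FALSE)
  } else {
    relations$pmid <- pmid
  }
  annotated_document(pmid, title, abstract, mentions, relations)
}
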
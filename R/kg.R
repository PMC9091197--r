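#' Assemble an evidence-backed knowledge graph
#'
#' Collects typed entities and relation triplets from annotated documents
#' (gold annotations or relation-classifier output written back into the
#' documents). Entities are deduplicated by entity id (all surface forms
#' kept); relations are deduplicated by `(rtype, head_id, tail_id)`, each
#' document occurrence contributing one evidence record — the first sentence
#' in which both endpoint mentions occur, or the whole text as a flagged
#' fallback. A relation's support is the number of distinct articles
#' providing evidence: multiple independent studies reinforce a triplet.
#' Triplets violating the ontology signature (or with unresolvable
#' endpoints) are rejected and reported, never stored.
#'
#' @param docs list of `annotated_document` objects.
#' @param sep title/abstract separator.
#' @return object of class `knowledge_graph`: list with `entities`
#'   (data.frame `entity_id`, `etype`, `name`, `surfaces` list-column) and
#'   `relations` (data.frame `rtype`, `head_id`, `tail_id`, `support`,
#'   `evidence` list-column of data.frames `pmid`, `sentence`,
#'   `whole_doc`). Rejected triplets are in `attr(, "rejected")`.
#' @export
assemble_graph <- function(docs, sep = " ") {
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  ent <- new.env(parent = emptyenv())       # entity_id -> list(etype, surfaces)
  rel <- new.env(parent = emptyenv())       # key -> list(rtype, h, t, evidence)
  rejected <- list()
  for (doc in docs) {
    m <- doc$mentions
    for (i in seq_len(nrow(m))) {
      id <- m$entity_id[i]
      cur <- ent[[id]]
      if (is.null(cur)) {
        ent[[id]] <- list(etype = m$etype[i], surfaces = m$text[i])
      } else {
        ent[[id]]$surfaces <- union(cur$surfaces, m$text[i])
      }
    }
    if (!nrow(doc$relations)) next
    text <- doc_text(doc, sep = sep)
    sents <- split_sentences(text)
    r <- doc$relations
    for (i in seq_len(nrow(r))) {
      h <- ent[[r$head_id[i]]]
      t <- ent[[r$tail_id[i]]]
      ok <- !is.null(h) && !is.null(t) &&
            is_valid_triplet(h$etype, t$etype, r$rtype[i])
      if (!ok) {
        rejected[[length(rejected) + 1L]] <- data.frame(
          pmid = doc$pmid, rtype = r$rtype[i], head_id = r$head_id[i],
          tail_id = r$tail_id[i], stringsAsFactors = FALSE)
        next
      }
      # evidence: first sentence containing mentions of both endpoints
      hm <- m[m$entity_id == r$head_id[i], , drop = FALSE]
      tm <- m[m$entity_id == r$tail_id[i], , drop = FALSE]
      sent <- NA_character_
      for (s in seq_len(nrow(sents))) {
        lo <- sents$start[s]; hi <- sents$end[s]
        if (any(hm$start >= lo & hm$end <= hi) &&
            any(tm$start >= lo & tm$end <= hi)) {
          sent <- sents$sentence[s]
          break
        }
      }
      whole <- is.na(sent)
      if (whole) sent <- text
      ev <- data.frame(pmid = doc$pmid, sentence = sent, whole_doc = whole,
                       stringsAsFactors = FALSE)
      key <- paste(r$rtype[i], r$head_id[i], r$tail_id[i], sep = "\r")
      cur <- rel[[key]]
      if (is.null(cur)) {
        rel[[key]] <- list(rtype = r$rtype[i], head_id = r$head_id[i],
                           tail_id = r$tail_id[i], evidence = ev)
      } else {
        rel[[key]]$evidence <- rbind(cur$evidence, ev)
      }
    }
  }
  ids <- sort(ls(ent))
  entities <- data.frame(
    entity_id = ids,
    etype = vapply(ids, function(i) ent[[i]]$etype, ""),
    name = vapply(ids, function(i) ent[[i]]$surfaces[1L], ""),
    stringsAsFactors = FALSE, row.names = NULL)
  entities$surfaces <- I(lapply(ids, function(i) ent[[i]]$surfaces))
  keys <- sort(ls(rel))
  relations <- data.frame(
    rtype = vapply(keys, function(k) rel[[k]]$rtype, ""),
    head_id = vapply(keys, function(k) rel[[k]]$head_id, ""),
    tail_id = vapply(keys, function(k) rel[[k]]$tail_id, ""),
    support = vapply(keys, function(k) length(unique(rel[[k]]$evidence$pmid)), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  relations$evidence <- I(lapply(keys, function(k) rel[[k]]$evidence))
  kg <- structure(list(entities = entities, relations = relations),
                  class = "knowledge_graph")
  attr(kg, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(pmid = character(), rtype = character(),
               head_id = character(), tail_id = character(),
               stringsAsFactors = FALSE)
  if (length(rejected)) {
    message(sprintf("assemble_graph: rejected %d invalid triplet(s)",
                    length(rejected)))
  }
  kg
}

#' @export
print.knowledge_graph <- function(x, ...) {
  tab <- table(x$entities$etype)
  cat(sprintf("<knowledge_graph: %d entity(ies) [%s], %d relation(s)>\n",
              nrow(x$entities),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$relations)))
  invisible(x)
}

kg_name <- function(kg, ids) {
  kg$entities$name[match(ids, kg$entities$entity_id)]
}

# partners of `ids` over edges of `rtype`: from head to tail or back
kg_step <- function(kg, ids, rtype, from = c("head", "tail")) {
  from <- match.arg(from)
  r <- kg$relations[kg$relations$rtype == rtype, , drop = FALSE]
  if (from == "head") unique(r$tail_id[r$head_id %in% ids])
  else unique(r$head_id[r$tail_id %in% ids])
}

# genes reachable from a herb through its chemicals (HHC then CAG)
herb_gene_set <- function(kg, herb_id) {
  kg_step(kg, kg_step(kg, herb_id, "HHC", "head"), "CAG", "head")
}

herb_disease_set <- function(kg, herb_id) {
  kg_step(kg, herb_id, "HTD", "head")
}

#' Degree rankings over the knowledge graph
#'
#' Descriptive rankings for dashboard-style summaries: herbs by the number
#' of distinct genes their chemicals associate with (herb -> HHC ->
#' chemical -> CAG -> gene paths), genes by the number of herbs reaching
#' them, herbs by diseases treated (direct HTD edges) and diseases by herbs
#' treating them. Ordered by count descending, ties alphabetical by entity
#' name; `k` larger than the candidate count returns the full list.
#'
#' @param kg a [assemble_graph()] result.
#' @param query one of `herb_by_genes`, `gene_by_herbs`, `herb_by_diseases`,
#'   `disease_by_herbs`.
#' @param k number of rows to return (default all).
#' @return data.frame with `entity_id`, `name`, `count` (entities with
#'   count 0 are omitted).
#' @export
degree_rankings <- function(kg, query = c("herb_by_genes", "gene_by_herbs",
                                          "herb_by_diseases",
                                          "disease_by_herbs"),
                            k = Inf) {
  query <- match.arg(query)
  e <- kg$entities
  src_type <- switch(query, herb_by_genes = "Herb", gene_by_herbs = "Gene",
                     herb_by_diseases = "Herb", disease_by_herbs = "Disease")
  ids <- e$entity_id[e$etype == src_type]
  count_for <- switch(query,
    herb_by_genes = function(id) length(herb_gene_set(kg, id)),
    gene_by_herbs = function(id) {
      chems <- kg_step(kg, id, "CAG", "tail")
      length(kg_step(kg, chems, "HHC", "tail"))
    },
    herb_by_diseases = function(id) length(herb_disease_set(kg, id)),
    disease_by_herbs = function(id) length(kg_step(kg, id, "HTD", "tail")))
  counts <- vapply(ids, count_for, 0L)
  out <- data.frame(entity_id = ids, name = kg_name(kg, ids),
                    count = as.integer(counts), stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[out$count > 0L, , drop = FALSE]
  out <- out[order(-out$count, out$name), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n = if (is.finite(k)) k else nrow(out))
}

#' Evidence for a relation
#'
#' @param kg a [assemble_graph()] result.
#' @param head_id,tail_id entity ids.
#' @param rtype relation label.
#' @return data.frame of evidence records (`pmid`, `sentence`,
#'   `whole_doc`), ordered by pmid; zero rows when the relation is absent.
#' @export
evidence_query <- function(kg, head_id, tail_id, rtype) {
  r <- kg$relations
  i <- which(r$rtype == rtype & r$head_id == head_id & r$tail_id == tail_id)
  if (!length(i)) {
    return(data.frame(pmid = character(), sentence = character(),
                      whole_doc = logical(), stringsAsFactors = FALSE))
  }
  ev <- r$evidence[[i]]
  ev <- ev[order(ev$pmid), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)   # empty union: flagged, contributes 0
  length(intersect(a, b)) / u
}

#' Biological similarity of two herbs
#'
#' The score is the half-sum of two Jaccard indices: over the gene sets the
#' herbs regulate through their chemicals (HHC followed by CAG paths) and
#' over the disease sets they treat (HTD edges):
#' `sim(i,j) = 1/2 * (|SG_i n SG_j| / |SG_i u SG_j| +
#' |SD_i n SD_j| / |SD_i u SD_j|)`. A term whose union is empty contributes
#' 0 and is flagged in `attr(, "empty_terms")`.
#'
#' @param kg a [assemble_graph()] result.
#' @param herb_i,herb_j entity ids of two herbs present in the graph.
#' @return numeric in \[0, 1\].
#' @export
herb_similarity <- function(kg, herb_i, herb_j) {
  e <- kg$entities
  for (h in c(herb_i, herb_j)) {
    if (!h %in% e$entity_id[e$etype == "Herb"]) {
      stop(sprintf("herb '%s' is not in the graph", h))
    }
  }
  jg <- jaccard(herb_gene_set(kg, herb_i), herb_gene_set(kg, herb_j))
  jd <- jaccard(herb_disease_set(kg, herb_i), herb_disease_set(kg, herb_j))
  empty <- c("genes", "diseases")[c(is.na(jg), is.na(jd))]
  score <- ((if (is.na(jg)) 0 else jg) + (if (is.na(jd)) 0 else jd)) / 2
  attr(score, "empty_terms") <- empty
  score
}

#' Rank herbs most similar to a query herb
#'
#' @param kg a [assemble_graph()] result.
#' @param herb entity id of the query herb.
#' @param k number of rows (default all other herbs).
#' @return data.frame `entity_id`, `name`, `score`, descending by score,
#'   ties alphabetical by name.
#' @export
rank_similar_herbs <- function(kg, herb, k = Inf) {
  e <- kg$entities
  if (!herb %in% e$entity_id[e$etype == "Herb"]) {
    stop(sprintf("herb '%s' is not in the graph", herb))
  }
  others <- setdiff(e$entity_id[e$etype == "Herb"], herb)
  scores <- vapply(others, function(o) as.numeric(herb_similarity(kg, herb, o)), 0)
  out <- data.frame(entity_id = others, name = kg_name(kg, others),
                    score = scores, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(-out$score, out$name), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n = if (is.finite(k)) k else nrow(out))
}

#' Gene-mediated drug-repurposing candidates
#'
#' Chemicals proposed for a disease through shared genes: locate the
#' disease, collect the genes linked to it by GID, collect the chemicals
#' linked to those genes by CAG, and drop any chemical already connected to
#' the disease by a direct CAD edge. Candidates are ranked by the number of
#' shared genes, descending, ties alphabetical by name.
#'
#' @param kg a [assemble_graph()] result.
#' @param disease_id entity id of a disease present in the graph.
#' @return data.frame `entity_id`, `name`, `shared_genes`.
#' @export
repurposing_candidates <- function(kg, disease_id) {
  e <- kg$entities
  if (!disease_id %in% e$entity_id[e$etype == "Disease"]) {
    stop(sprintf("disease '%s' is not in the graph", disease_id))
  }
  genes <- kg_step(kg, disease_id, "GID", "tail")      # GID: gene -> disease
  if (!length(genes)) {
    return(data.frame(entity_id = character(), name = character(),
                      shared_genes = integer(), stringsAsFactors = FALSE))
  }
  cag <- kg$relations[kg$relations$rtype == "CAG" &
                      kg$relations$tail_id %in% genes, , drop = FALSE]
  direct <- kg_step(kg, disease_id, "CAD", "tail")     # chemicals with CAD
  cand <- setdiff(unique(cag$head_id), direct)
  if (!length(cand)) {
    return(data.frame(entity_id = character(), name = character(),
                      shared_genes = integer(), stringsAsFactors = FALSE))
  }
  shared <- vapply(cand, function(cid) {
    length(unique(cag$tail_id[cag$head_id == cid]))
  }, 0L)
  out <- data.frame(entity_id = cand, name = kg_name(kg, cand),
                    shared_genes = as.integer(shared),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$shared_genes, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the knowledge graph
#'
#' `as_igraph` builds a directed igraph with node attributes `etype` and
#' `name` and edge attributes `rtype`, `support` and the supporting pmids;
#' `write_kg_graphml` serializes it as GraphML; `write_kg_tables` writes
#' node and edge CSV tables suitable for bulk import into common graph
#' databases.
#'
#' @param kg a [assemble_graph()] result.
#' @return an igraph object.
#' @export
as_igraph <- function(kg) {
  nodes <- kg$entities[, c("entity_id", "etype", "name")]
  names(nodes)[1L] <- "name_id"
  edges <- data.frame(
    from = kg$relations$head_id, to = kg$relations$tail_id,
    rtype = kg$relations$rtype, support = kg$relations$support,
    pmids = vapply(kg$relations$evidence,
                   function(ev) paste(unique(ev$pmid), collapse = "|"), ""),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = nodes$name_id, etype = nodes$etype,
                          label = nodes$name, stringsAsFactors = FALSE))
}

#' @rdname as_igraph
#' @param path output GraphML file.
#' @export
write_kg_graphml <- function(kg, path) {
  igraph::write_graph(as_igraph(kg), path, format = "graphml")
  invisible(path)
}

#' @rdname as_igraph
#' @param nodes_path,edges_path output CSV files.
#' @export
write_kg_tables <- function(kg, nodes_path, edges_path) {
  nodes <- kg$entities[, c("entity_id", "etype", "name")]
  nodes$surfaces <- vapply(kg$entities$surfaces, paste, "", collapse = "|")
  write.csv(nodes, nodes_path, row.names = FALSE)
  edges <- kg$relations[, c("rtype", "head_id", "tail_id", "support")]
  edges$evidence_pmids <- vapply(kg$relations$evidence,
                                 function(ev) paste(unique(ev$pmid),
                                                    collapse = "|"), "")
  write.csv(edges, edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}
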
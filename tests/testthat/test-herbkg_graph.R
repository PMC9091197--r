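# build a knowledge graph from a bare edge list: one synthetic document per
# edge, entity types/names derived from the id prefix (H/C/D/G)
kg_from_edges <- function(edges) {
  ename <- function(id) paste0("ent ", tolower(id))
  etype_of <- function(id) {
    switch(substr(id, 1L, 1L), H = "Herb", C = "Chemical", D = "Disease",
           G = "Gene")
  }
  docs <- lapply(seq_len(nrow(edges)), function(i) {
    h <- edges$head_id[i]; t <- edges$tail_id[i]
    make_doc(sprintf("80%04d", i), "Edge note.",
             sprintf("%s relates to %s here.", ename(h), ename(t)),
             data.frame(text = c(ename(h), ename(t)),
                        etype = c(etype_of(h), etype_of(t)),
                        entity_id = c(h, t), stringsAsFactors = FALSE),
             data.frame(rtype = edges$rtype[i], head_id = h, tail_id = t,
                        stringsAsFactors = FALSE))
  })
  assemble_graph(docs)
}

oxymatrine_doc <- function() {
  title <- "Oxymatrine attenuates microglial inflammation."
  abstract <- paste(
    "Oxymatrine (OMT) is an alkaloid extracted from Sophora flavescens",
    "with anti-inflammatory properties.",
    "Western blot analysis and ELISA showed that OMT decreased the",
    "expression and release of HSP60 by LPS-activated BV2 cells.",
    "OMT may therefore offer substantial therapeutic potential for",
    "treating neurodegenerative diseases in several models.")
  make_doc("27882228", title, abstract,
           data.frame(text = c("Sophora flavescens", "Oxymatrine", "OMT",
                               "HSP60", "neurodegenerative diseases"),
                      etype = c("Herb", "Chemical", "Chemical", "Gene",
                                "Disease"),
                      entity_id = c("H_SF", "C_OMT", "C_OMT", "G_HSP60",
                                    "D_ND"),
                      stringsAsFactors = FALSE),
           data.frame(rtype = c("HHC", "CAG", "CAD"),
                      head_id = c("H_SF", "C_OMT", "C_OMT"),
                      tail_id = c("C_OMT", "G_HSP60", "D_ND"),
                      stringsAsFactors = FALSE))
}

test_that("assembly attaches co-occurrence sentences as evidence", {
  kg <- assemble_graph(list(oxymatrine_doc()))
  hhc <- evidence_query(kg, "H_SF", "C_OMT", "HHC")
  expect_equal(nrow(hhc), 1L)
  expect_match(hhc$sentence,
               "Oxymatrine \\(OMT\\) is an alkaloid extracted from Sophora flavescens")
  cag <- evidence_query(kg, "C_OMT", "G_HSP60", "CAG")
  expect_match(cag$sentence, "OMT decreased the expression and release of HSP60")
  expect_false(any(c(hhc$whole_doc, cag$whole_doc)))
  expect_equal(nrow(evidence_query(kg, "C_OMT", "G_HSP60", "CAD")), 0L)
})

test_that("repeated triplets merge into one relation with higher support", {
  d1 <- oxymatrine_doc()
  d2 <- oxymatrine_doc()
  d2$pmid <- "99999999"
  d2$mentions$pmid <- d2$pmid
  d2$relations$pmid <- d2$pmid
  kg <- assemble_graph(list(d1, d2))
  r <- kg$relations[kg$relations$rtype == "HHC", ]
  expect_equal(nrow(r), 1L)
  expect_equal(r$support, 2L)
  ev <- evidence_query(kg, "H_SF", "C_OMT", "HHC")
  expect_equal(nrow(ev), 2L)                 # one record per pmid
  expect_equal(ev$pmid, sort(ev$pmid))
})

test_that("signature-violating triplets are rejected, not stored", {
  doc <- oxymatrine_doc()
  doc$relations <- rbind(doc$relations,
                         data.frame(pmid = doc$pmid, rtype = "HHC",
                                    head_id = "G_HSP60", tail_id = "D_ND",
                                    stringsAsFactors = FALSE))
  expect_message(kg <- assemble_graph(list(doc)), "rejected")
  expect_equal(nrow(kg$relations), 3L)
  expect_equal(nrow(attr(kg, "rejected")), 1L)
  # every stored relation satisfies the ontology signature
  et <- kg$entities$etype[match(kg$relations$head_id, kg$entities$entity_id)]
  tt <- kg$entities$etype[match(kg$relations$tail_id, kg$entities$entity_id)]
  for (i in seq_len(nrow(kg$relations))) {
    expect_true(is_valid_triplet(et[i], tt[i], kg$relations$rtype[i]))
  }
})

test_that("assembly recovers the planted graph exactly on generated corpora", {
  cp <- generate_corpus(generator_spec(seed = 61L, n_docs = 30L))
  kg <- assemble_graph(cp$docs)
  key <- function(d) sort(paste(d$rtype, d$head_id, d$tail_id))
  expect_equal(key(kg$relations), key(cp$truth$relations))
  expect_true(all(kg$relations$support >= 1L))
  # support equals evidence count when each pmid contributes once
  for (i in seq_len(nrow(kg$relations))) {
    ev <- kg$relations$evidence[[i]]
    expect_equal(kg$relations$support[i], length(unique(ev$pmid)))
  }
})

test_that("degree rankings traverse chemical-mediated herb-gene paths", {
  kg <- kg_from_edges(data.frame(
    rtype = c("HHC", "HHC", "CAG", "CAG", "CAG", "HHC", "CAG",
              "HTD", "HTD"),
    head_id = c("H1", "H1", "C1", "C1", "C2", "H2", "C3",
                "H1", "H2"),
    tail_id = c("C1", "C2", "G1", "G2", "G3", "C3", "G1",
                "D1", "D1"),
    stringsAsFactors = FALSE))
  hg <- degree_rankings(kg, "herb_by_genes")
  expect_equal(hg$entity_id, c("H1", "H2"))
  expect_equal(hg$count, c(3L, 1L))
  gh <- degree_rankings(kg, "gene_by_herbs")
  expect_equal(gh$count[gh$entity_id == "G1"], 2L)
  dh <- degree_rankings(kg, "disease_by_herbs")
  expect_equal(dh$count, 2L)
  expect_equal(nrow(degree_rankings(kg, "herb_by_genes", k = 1L)), 1L)
  expect_equal(nrow(degree_rankings(kg, "herb_by_genes", k = 50L)), 2L)
  empty <- assemble_graph(list())
  expect_equal(nrow(degree_rankings(empty, "herb_by_genes")), 0L)
  expect_error(degree_rankings(kg, "bogus"))
})

test_that("herb similarity is the half-sum of gene and disease Jaccard terms", {
  # SG_i = {g1,g2,g3}, SG_j = {g2,g3}; SD_i = SD_j = {d1}
  kg <- kg_from_edges(data.frame(
    rtype = c("HHC", "CAG", "CAG", "CAG", "HHC", "CAG", "CAG",
              "HTD", "HTD"),
    head_id = c("H1", "C1", "C1", "C1", "H2", "C2", "C2", "H1", "H2"),
    tail_id = c("C1", "G1", "G2", "G3", "C2", "G2", "G3", "D1", "D1"),
    stringsAsFactors = FALSE))
  s <- herb_similarity(kg, "H1", "H2")
  expect_equal(as.numeric(s), 0.5 * (2 / 3 + 1))
  expect_length(attr(s, "empty_terms"), 0L)
  expect_equal(as.numeric(herb_similarity(kg, "H1", "H1")), 1.0)
  expect_error(herb_similarity(kg, "H1", "H9"), "not in the graph")
})

test_that("disjoint and profile-free herbs score zero with flags", {
  kg <- kg_from_edges(data.frame(
    rtype = c("HHC", "CAG", "HHC", "CAG", "HTD", "HTD"),
    head_id = c("H1", "C1", "H2", "C2", "H1", "H2"),
    tail_id = c("C1", "G1", "C2", "G2", "D1", "D2"),
    stringsAsFactors = FALSE))
  expect_equal(as.numeric(herb_similarity(kg, "H1", "H2")), 0)
  # herbs with no gene profile at all: the gene term is flagged empty
  kg2 <- kg_from_edges(data.frame(rtype = c("HTD", "HTD"),
                                  head_id = c("H1", "H2"),
                                  tail_id = c("D1", "D1"),
                                  stringsAsFactors = FALSE))
  s <- herb_similarity(kg2, "H1", "H2")
  expect_equal(as.numeric(s), 0.5)
  expect_equal(attr(s, "empty_terms"), "genes")
})

test_that("similarity rankings agree with brute-force pairwise scoring", {
  cp <- generate_corpus(generator_spec(seed = 67L, n_docs = 40L,
                                       relation_mix = c(HHC = 1, HTD = 1,
                                                        CAD = 0.2, CAG = 1,
                                                        GID = 0.2)))
  kg <- assemble_graph(cp$docs)
  herbs <- kg$entities$entity_id[kg$entities$etype == "Herb"]
  expect_gt(length(herbs), 2L)
  # symmetry sweep
  for (i in seq_len(min(5L, length(herbs) - 1L))) {
    a <- herbs[i]; b <- herbs[i + 1L]
    sa <- as.numeric(herb_similarity(kg, a, b))
    expect_equal(sa, as.numeric(herb_similarity(kg, b, a)))
    expect_gte(sa, 0); expect_lte(sa, 1)
  }
  q <- herbs[1L]
  rk <- rank_similar_herbs(kg, q, k = 3L)
  brute <- vapply(setdiff(herbs, q), function(o) {
    as.numeric(herb_similarity(kg, q, o))
  }, 0)
  expect_equal(rk$score[1L], max(brute))
  expect_lte(nrow(rk), 3L)
  lone <- kg_from_edges(data.frame(rtype = "HTD", head_id = "H1",
                                   tail_id = "D1", stringsAsFactors = FALSE))
  expect_equal(nrow(rank_similar_herbs(lone, "H1")), 0L)
})

test_that("repurposing walks disease-gene-chemical paths and excludes direct edges", {
  kg <- kg_from_edges(data.frame(
    rtype = c("GID", "CAG", "CAG", "CAD", "GID", "CAG"),
    head_id = c("G1", "C1", "C2", "C2", "G2", "C1"),
    tail_id = c("D1", "G1", "G1", "D1", "D1", "G2"),
    stringsAsFactors = FALSE))
  cand <- repurposing_candidates(kg, "D1")
  # C2 acts on D1 directly, so only C1 (sharing G1 and G2) qualifies
  expect_equal(cand$entity_id, "C1")
  expect_equal(cand$shared_genes, 2L)
  no_gid <- kg_from_edges(data.frame(rtype = c("CAD"), head_id = "C1",
                                     tail_id = "D1", stringsAsFactors = FALSE))
  expect_equal(nrow(repurposing_candidates(no_gid, "D1")), 0L)
  expect_error(repurposing_candidates(kg, "D9"), "not in the graph")
})

test_that("chemicals with a direct disease edge never appear as candidates", {
  set.seed(71)
  for (rep in 1:5) {
    n_g <- sample(2:4, 1); n_c <- sample(2:5, 1)
    edges <- data.frame(rtype = "GID",
                        head_id = paste0("G", seq_len(n_g)),
                        tail_id = "D1", stringsAsFactors = FALSE)
    for (c in paste0("C", seq_len(n_c))) {
      for (g in sample(paste0("G", seq_len(n_g)), sample(n_g, 1))) {
        edges <- rbind(edges, data.frame(rtype = "CAG", head_id = c,
                                         tail_id = g))
      }
    }
    direct <- sample(paste0("C", seq_len(n_c)), sample(n_c, 1))
    for (c in direct) {
      edges <- rbind(edges, data.frame(rtype = "CAD", head_id = c,
                                       tail_id = "D1"))
    }
    cand <- repurposing_candidates(kg_from_edges(edges), "D1")
    expect_false(any(cand$entity_id %in% direct))
  }
})

test_that("graph exports carry nodes, edges, support and evidence pmids", {
  kg <- assemble_graph(list(oxymatrine_doc()))
  g <- as_igraph(kg)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  gml <- tempfile(fileext = ".graphml")
  write_kg_graphml(kg, gml)
  expect_true(file.exists(gml) && file.size(gml) > 0)
  np <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  write_kg_tables(kg, np, ep)
  nodes <- utils::read.csv(np, stringsAsFactors = FALSE)
  edges <- utils::read.csv(ep, stringsAsFactors = FALSE)
  expect_setequal(nodes$entity_id, c("H_SF", "C_OMT", "G_HSP60", "D_ND"))
  expect_true(all(edges$evidence_pmids == "27882228"))
})
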
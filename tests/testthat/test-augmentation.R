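test_that("Substitution I templates the chemical-gene pathway sentence exactly", {
  corp <- extract_template_corpus(cag_pathway_doc(), "CAG")
  expect_true(paste("[Chemical] induces apoptosis via inhibition of the",
                    "[Gene] signaling pathway.") %in% corp$text)
})

test_that("relations never co-occurring in one sentence yield no templates", {
  doc <- make_doc("77", "Herba beta overview.",
                  paste("Herba beta was studied. Separately, chemol x was",
                        "measured."),
                  data.frame(text = c("Herba beta", "chemol x"),
                             etype = c("Herb", "Chemical"),
                             entity_id = c("H1", "C1"),
                             stringsAsFactors = FALSE),
                  data.frame(rtype = "HHC", head_id = "H1", tail_id = "C1",
                             stringsAsFactors = FALSE))
  expect_equal(nrow(extract_template_corpus(doc, "HHC")), 0L)
})

test_that("every extracted template carries both signature placeholders", {
  cp <- generate_corpus(generator_spec(seed = 41L, n_docs = 30L,
                                       relation_mix = c(HHC = 1, HTD = 1,
                                                        CAD = 1, CAG = 1,
                                                        GID = 1)))
  for (rt in setdiff(relation_types(), "Neg")) {
    corp <- extract_template_corpus(cp$docs, rt)
    if (!nrow(corp)) next
    sig <- relation_signature(rt)
    expect_true(all(grepl(paste0("\\[", sig[1L], "\\]"), corp$text)))
    expect_true(all(grepl(paste0("\\[", sig[2L], "\\]"), corp$text)))
  }
})

test_that("generated templates keep exactly one placeholder of each type", {
  cp <- generate_corpus(generator_spec(seed = 43L, n_docs = 30L,
                                       relation_mix = c(HHC = 1, HTD = 1,
                                                        CAD = 1, CAG = 1,
                                                        GID = 1)))
  corp <- extract_template_corpus(cp$docs, "CAG")
  expect_gt(nrow(corp), 0L)
  tpl <- generate_templates(corp, 25L, seed = 2L)
  expect_equal(nrow(tpl), 25L)
  count <- function(x, ph) lengths(regmatches(x, gregexpr(ph, x, fixed = TRUE)))
  expect_true(all(count(tpl$text, "[Chemical]") == 1L))
  expect_true(all(count(tpl$text, "[Gene]") == 1L))
  expect_identical(tpl, generate_templates(corp, 25L, seed = 2L))
  expect_equal(nrow(generate_templates(corp, 0L, seed = 2L)), 0L)
  expect_error(generate_templates(corp[0, ], 5L), "empty")
})

test_that("Substitution II realizes the flavonoid example with a sound label", {
  tpl <- data.frame(text = paste("[Chemical] reduced myocardial infarction",
                                 "area and attenuated [Gene] production."),
                    rtype = "CAG", source = "generated",
                    stringsAsFactors = FALSE)
  db <- entity_db(data.frame(etype = c("Chemical", "Gene"),
                             text = c("Flavonoids", "TNF-alpha"),
                             stringsAsFactors = FALSE),
                  data.frame(rtype = "CAG", head_text = "Flavonoids",
                             tail_text = "TNF-alpha",
                             stringsAsFactors = FALSE))
  out <- substitution_two(tpl, db, seed = 1L)
  expect_equal(out$sentence_a,
               paste("Flavonoids reduced myocardial infarction area and",
                     "attenuated TNF-alpha production."))
  expect_equal(out$label, "CAG")
  expect_equal(out$sentence_b, "Flavonoids TNF-alpha")
  expect_equal(out$origin, "augmented")
})

test_that("every realized pair is a known related pair of its label", {
  cp <- generate_corpus(generator_spec(seed = 47L, n_docs = 40L,
                                       relation_mix = c(HHC = 1, HTD = 1,
                                                        CAD = 1, CAG = 1,
                                                        GID = 1)))
  db <- entity_db_from_docs(cp$docs)
  for (rt in setdiff(relation_types(), "Neg")) {
    corp <- extract_template_corpus(cp$docs, rt)
    if (!nrow(corp)) next
    out <- substitution_two(generate_templates(corp, 15L, seed = 3L), db,
                            seed = 4L)
    known <- db$pairs[db$pairs$rtype == rt, ]
    expect_true(all(paste(out$head_text, out$tail_text) %in%
                    paste(known$head_text, known$tail_text)))
    expect_true(all(out$label == rt))
  }
})

test_that("templates with no known pair are skipped with a message", {
  tpl <- data.frame(text = "[Herb] contains [Chemical].", rtype = "HHC",
                    source = "generated", stringsAsFactors = FALSE)
  db <- entity_db(data.frame(etype = c("Chemical", "Gene"),
                             text = c("x", "y"), stringsAsFactors = FALSE),
                  data.frame(rtype = "CAG", head_text = "x", tail_text = "y",
                             stringsAsFactors = FALSE))
  expect_message(out <- substitution_two(tpl, db, seed = 1L), "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("a single-pair database realizes every template with that pair", {
  tpl <- data.frame(text = rep("[Herb] contains [Chemical].", 5L),
                    rtype = "HHC", source = "generated",
                    stringsAsFactors = FALSE)
  db <- entity_db(data.frame(etype = c("Herb", "Chemical"),
                             text = c("Herba z", "chemol q"),
                             stringsAsFactors = FALSE),
                  data.frame(rtype = "HHC", head_text = "Herba z",
                             tail_text = "chemol q", stringsAsFactors = FALSE))
  out <- substitution_two(tpl, db, seed = 9L)
  expect_equal(unique(out$sentence_a), "Herba z contains chemol q.")
})

test_that("pairs violating the signature are rejected by the database", {
  expect_error(
    entity_db(data.frame(etype = c("Gene", "Chemical"),
                         text = c("g", "c"), stringsAsFactors = FALSE),
              data.frame(rtype = "HHC", head_text = "g", tail_text = "c",
                         stringsAsFactors = FALSE)),
    "signature")
})

test_that("augmentation appends training-only examples conservatively", {
  cp <- generate_corpus(generator_spec(seed = 53L, n_docs = 30L))
  db <- entity_db_from_docs(cp$docs)
  train <- build_examples(cp$docs)
  expect_identical(augment_training_set(train, cp$docs, db, 0L), train)
  aug <- augment_training_set(train, cp$docs, db, n_per_rtype = 5L, seed = 2L)
  n_new <- nrow(aug) - nrow(train)
  expect_gt(n_new, 0L)
  expect_identical(as.data.frame(aug[seq_len(nrow(train)), ]),
                   as.data.frame(train))
  expect_true(all(aug$origin[-seq_len(nrow(train))] == "augmented"))
})

test_that("entity databases round-trip through their TSV dialect", {
  cp <- generate_corpus(generator_spec(seed = 59L, n_docs = 10L))
  db <- entity_db_from_docs(cp$docs)
  ep <- tempfile(fileext = ".tsv"); pp <- tempfile(fileext = ".tsv")
  utils::write.table(db$entities, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(db$pairs, pp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back <- read_entity_db(ep, pp)
  expect_equal(back$pairs[order(back$pairs$head_text), ],
               db$pairs[order(db$pairs$head_text), ],
               ignore_attr = TRUE)
})
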
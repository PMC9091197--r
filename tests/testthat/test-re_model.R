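tiny <- encoder_preset("tiny")

test_that("sentence-pair encoding follows the A/sep/B/sep layout", {
  tok <- build_tokenizer(c("short title. short abstract.",
                           "cassia bark cinnamaldehyde"))
  pr <- tokenize_pair("short title. short abstract.",
                      "cassia bark cinnamaldehyde", tok, tiny)
  # the segment id switches exactly once, right after sentence A's separator
  expect_equal(sum(diff(pr$segment) != 0L), 1L)
  expect_equal(which(diff(pr$segment) != 0L), pr$sep_positions[1L])
  expect_equal(pr$tokens[pr$sep_positions], rep("[sep]", 2L))
  expect_equal(pr$position, seq_along(pr$tokens))

  empty_a <- tokenize_pair("", "cassia bark", tok, tiny)
  expect_equal(length(empty_a$tokens), 4L)   # sep + two B tokens + sep
  expect_equal(empty_a$tokens[1L], "[sep]")
})

test_that("sentence B survives truncation and detokenizes exactly", {
  tok <- build_tokenizer("a b c d e f g h i j k l m n o p q r s t")
  cfg <- encoder_config(num_layers = 1L, num_heads = 1L, hidden_dim = 8L,
                        max_seq_len = 8L)
  pr <- tokenize_pair("a b c d e f g h i j", "k l", tok, cfg)
  expect_length(pr$tokens, 8L)
  expect_equal(pr$tokens[1:4], c("a", "b", "c", "d"))   # A head kept
  expect_equal(detokenize_sentence_b(pr), "k l")
  expect_error(tokenize_pair("a", paste(letters[1:10], collapse = " "),
                             tok, cfg), "sentence B")
  ex <- make_separable_re_set(3L, seed = 2L)
  tok2 <- build_tokenizer(c(ex$sentence_a, ex$sentence_b))
  for (i in seq_len(nrow(ex))) {
    pr2 <- tokenize_pair(example = ex[i, ], tokenizer = tok2, config = tiny)
    expect_equal(detokenize_sentence_b(pr2), ex$sentence_b[i])
  }
})

test_that("prediction distributions are valid on arbitrary inputs", {
  ex <- make_separable_re_set(2L, seed = 3L)
  st0 <- train_classifier(ex, tiny, train_config(epochs = 0L, seed = 5L))
  probs <- predict(st0, ex)
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, nrow(ex)), tolerance = 1e-6)
  # inference determinism
  expect_identical(predict(st0, ex), predict(st0, ex))
  # zero learning rate leaves the untrained state intact
  st_lr0 <- train_classifier(ex, tiny,
                             train_config(epochs = 1L, learning_rate = 0,
                                          seed = 5L))
  expect_equal(predict(st_lr0, ex), probs)
})

test_that("labels outside the six-class set are rejected before training", {
  ex <- make_separable_re_set(1L, seed = 3L)
  ex$label[1L] <- "BOGUS"
  expect_error(train_classifier(ex, tiny, train_config(epochs = 1L)),
               "six-class")
})

test_that("the tiny preset overfits the separable fixture to 100% accuracy", {
  ex <- separable_training_set()
  st <- trained_tiny_classifier()
  pred <- predict_labels(st, ex)
  expect_equal(mean(pred == ex$label), 1.0)
  # the argmax of every training example's distribution is its gold label
  probs <- predict(st, ex)
  expect_equal(colnames(probs)[max.col(probs)], ex$label)
})

test_that("uniform class weights reproduce plain cross-entropy training", {
  # balanced labels give all-equal inverse-frequency weights (mean 1), so
  # weighted and plain cross-entropy must produce identical updates
  ex <- make_separable_re_set(3L, seed = 9L)
  cfg <- encoder_config(num_layers = 1L, num_heads = 2L, hidden_dim = 16L,
                        max_seq_len = 48L)
  a <- train_classifier(ex, cfg, train_config(epochs = 2L, seed = 4L,
                                              loss = "cross_entropy"))
  b <- train_classifier(ex, cfg, train_config(epochs = 2L, seed = 4L,
                                              loss = "weighted_cross_entropy"))
  expect_equal(a$params, b$params)
  expect_equal(a$loss, b$loss)
})

test_that("training is deterministic given the seed across optimizers", {
  ex <- make_separable_re_set(2L, seed = 6L)
  cfg <- encoder_config(num_layers = 1L, num_heads = 2L, hidden_dim = 16L,
                        max_seq_len = 48L)
  for (opt in c("sgd", "momentum", "adam")) {
    a <- train_classifier(ex, cfg, train_config(epochs = 2L, seed = 8L,
                                                optimizer = opt))
    b <- train_classifier(ex, cfg, train_config(epochs = 2L, seed = 8L,
                                                optimizer = opt))
    expect_equal(a$loss, b$loss)
    expect_equal(a$params, b$params)
  }
})

test_that("masked-language fine-tuning reduces held-out loss deterministically", {
  cp <- generate_corpus(generator_spec(seed = 5L, n_docs = 40L))
  ck <- domain_finetune_mlm(cp$docs, tiny, steps = 40L, seed = 3L,
                            batch_size = 4L)
  expect_lt(ck$loss_after, ck$loss_before)
  ck2 <- domain_finetune_mlm(cp$docs, tiny, steps = 40L, seed = 3L,
                             batch_size = 4L)
  expect_equal(ck$loss_after, ck2$loss_after)
  ck0 <- domain_finetune_mlm(cp$docs, tiny, steps = 0L, seed = 3L)
  expect_equal(ck0$loss_before, ck0$loss_after)
})

test_that("an MLM checkpoint plugs into classifier training", {
  cp <- generate_corpus(generator_spec(seed = 23L, n_docs = 15L))
  ck <- domain_finetune_mlm(cp$docs, tiny, steps = 5L, seed = 2L)
  ex <- build_examples(cp$docs)
  st <- train_classifier(ex, tiny, train_config(epochs = 1L, seed = 2L),
                         checkpoint = ck)
  expect_identical(st$tokenizer, ck$tokenizer)
  probs <- predict(st, ex[1L, ])
  expect_equal(sum(probs), 1, tolerance = 1e-6)
})

test_that("the published tuning ranges enumerate 150 configurations", {
  g <- grid_configs()
  expect_equal(nrow(g), 150L)
  expect_equal(nrow(unique(g)), 5L * 5L * 2L * 3L)
  path <- tempfile(fileext = ".yaml")
  writeLines(c("epochs: [1, 3]", "learning_rate: [0.001]",
               "loss: [cross_entropy]", "optimizer: [adam]"), path)
  expect_equal(nrow(read_grid_yaml(path)), 2L)
})

test_that("grid search ranks configurations by macro-F1 with stable ties", {
  ex <- make_separable_re_set(4L, seed = 12L)
  sp <- split_train_test(ex, seed = 1L)
  cfg <- encoder_config(num_layers = 1L, num_heads = 2L, hidden_dim = 16L,
                        max_seq_len = 48L)
  grid <- grid_configs(epochs = c(1L, 6L), learning_rate = 1e-3,
                       loss = "cross_entropy", optimizer = "adam")
  gs <- grid_search(sp$train, sp$test, cfg, grid, seed = 5L)
  expect_equal(nrow(gs$results), 2L)
  expect_true(all(diff(gs$results$macro_f1) <= 0))
  # brute-force oracle: best F1 equals the max over an independent loop
  oracle <- vapply(seq_len(nrow(grid)), function(i) {
    st <- train_classifier(sp$train, cfg,
                           train_config(epochs = grid$epochs[i],
                                        learning_rate = grid$learning_rate[i],
                                        loss = grid$loss[i],
                                        optimizer = grid$optimizer[i],
                                        seed = 5L))
    cm <- confusion_matrix(sp$test$label, predict_labels(st, sp$test))
    class_metrics(cm)$summary$macro_f1
  }, 0)
  expect_equal(gs$results$macro_f1[1L], max(oracle))
  # single-point grid returns that configuration
  g1 <- grid_configs(epochs = 3L, learning_rate = 1e-3,
                     loss = "cross_entropy", optimizer = "sgd")
  gs1 <- grid_search(sp$train, sp$test, cfg, g1, seed = 5L)
  expect_equal(gs1$results$epochs, 3L)
})
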
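#' Training configuration
#'
#' One point of the training grid: epochs, learning rate, loss (plain or
#' class-weighted cross-entropy), optimizer (SGD, SGD with momentum 0.9, or
#' Adam), seed and batch size. When grid-searching, values are drawn from
#' the published tuning ranges (see [grid_configs()]); otherwise any values
#' are accepted.
#'
#' @param epochs number of passes over the training data.
#' @param learning_rate step size.
#' @param loss `"cross_entropy"` or `"weighted_cross_entropy"` (weights =
#'   inverse class frequency, normalized to mean 1 over present classes).
#' @param optimizer `"adam"`, `"sgd"` or `"momentum"`.
#' @param seed integer RNG seed (initialization and shuffling).
#' @param batch_size minibatch size.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 3L, learning_rate = 1e-3,
                         loss = c("cross_entropy", "weighted_cross_entropy"),
                         optimizer = c("adam", "sgd", "momentum"),
                         seed = 1L, batch_size = 8L) {
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 loss = match.arg(loss),
                 optimizer = match.arg(optimizer),
                 seed = as.integer(seed),
                 batch_size = as.integer(batch_size)),
            class = "train_config")
}

class_weights <- function(labels, scheme) {
  w <- stats::setNames(rep(1, length(ALL_RELATIONS)), ALL_RELATIONS)
  if (scheme == "weighted_cross_entropy") {
    counts <- table(factor(labels, levels = ALL_RELATIONS))
    present <- names(counts)[counts > 0L]
    inv <- 1 / as.numeric(counts[present])
    w[present] <- inv / mean(inv)    # normalized to mean 1
  }
  w
}

make_optimizer <- function(kind, lr, params) {
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  if (kind %in% c("momentum", "adam")) state$m <- zero_like(params)
  if (kind == "adam") state$v <- zero_like(params)
  step <- function(params, grads) {
    state$t <- state$t + 1L
    for (nmi in names(params)) {
      g <- grads[[nmi]]
      if (kind == "sgd") {
        params[[nmi]] <- params[[nmi]] - lr * g
      } else if (kind == "momentum") {
        state$m[[nmi]] <- 0.9 * state$m[[nmi]] + g
        params[[nmi]] <- params[[nmi]] - lr * state$m[[nmi]]
      } else {                     # adam
        state$m[[nmi]] <- 0.9 * state$m[[nmi]] + 0.1 * g
        state$v[[nmi]] <- 0.999 * state$v[[nmi]] + 0.001 * g^2
        mh <- state$m[[nmi]] / (1 - 0.9^state$t)
        vh <- state$v[[nmi]] / (1 - 0.999^state$t)
        params[[nmi]] <- params[[nmi]] - lr * mh / (sqrt(vh) + 1e-8)
      }
    }
    params
  }
  step
}

#' Train the six-class relation classifier
#'
#' Trains the transformer encoder of [encoder_config()] on sentence-pair
#' examples with cross-entropy (optionally class-weighted) and the chosen
#' optimizer. Deterministic given the configs' seeds. A checkpoint from
#' [domain_finetune_mlm()] (or a previously trained classifier) can seed the
#' tokenizer and encoder weights, playing the role of an externally
#' pretrained model.
#'
#' @param train an [re_examples()] data.frame (labels within the six-class
#'   set; checked before training).
#' @param enc an [encoder_config()].
#' @param tc a [train_config()].
#' @param checkpoint optional list with `tokenizer` and `params` (e.g. an
#'   `mlm_checkpoint`); defaults to `enc$pretrained_checkpoint`.
#' @return object of class `re_classifier`: list with `config`, `tokenizer`,
#'   `params`, `labels`, `weights` and the final epoch mean `loss`.
#' @export
train_classifier <- function(train, enc, tc = train_config(),
                             checkpoint = NULL) {
  stopifnot(inherits(enc, "encoder_config"), inherits(tc, "train_config"),
            nrow(train) >= 1L)
  bad <- setdiff(unique(train$label), ALL_RELATIONS)
  if (length(bad)) {
    stop("label(s) outside the six-class set: ", paste(bad, collapse = ", "))
  }
  checkpoint <- checkpoint %||% enc$pretrained_checkpoint
  if (is.null(checkpoint)) {
    tokenizer <- build_tokenizer(c(train$sentence_a, train$sentence_b))
    params <- init_params(enc, length(tokenizer$vocab), seed = tc$seed)
  } else {
    tokenizer <- checkpoint$tokenizer
    params <- checkpoint$params
  }
  w <- class_weights(train$label, tc$loss)
  pairs <- lapply(seq_len(nrow(train)), function(i) {
    tokenize_pair(example = train[i, , drop = FALSE], tokenizer = tokenizer,
                  config = enc)
  })
  y <- match(train$label, ALL_RELATIONS)
  n <- nrow(train)
  state <- list(config = enc, tokenizer = tokenizer, params = params,
                labels = ALL_RELATIONS, weights = w, loss = NA_real_)
  if (tc$epochs == 0L || tc$learning_rate == 0) {
    class(state) <- "re_classifier"
    return(state)
  }
  opt <- make_optimizer(tc$optimizer, tc$learning_rate, params)
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1L, n, by = tc$batch_size)) {
        batch <- ord[b0:min(b0 + tc$batch_size - 1L, n)]
        grads <- zero_like(params)
        for (i in batch) {
          fw <- encoder_forward(params, enc, pairs[[i]]$ids,
                                pairs[[i]]$segment)
          cf <- classify_forward(params, fw$H_out)
          wi <- w[[train$label[i]]]
          ep_loss <- ep_loss - wi * log(max(cf$probs[y[i]], 1e-12))
          dlogit <- cf$probs
          dlogit[y[i]] <- dlogit[y[i]] - 1
          dlogit <- wi * dlogit / length(batch)
          grads$Wc <- grads$Wc + outer(cf$h, dlogit)
          grads$bc <- grads$bc + dlogit
          dh <- drop(params$Wc %*% dlogit)
          nrow_h <- nrow(fw$H_out)
          dX2 <- matrix(dh / nrow_h, nrow_h, length(dh), byrow = TRUE)
          grads <- encoder_backward(params, enc, fw$cache, dX2, grads)
        }
        params <- opt(params, grads)
      }
      state$loss <- ep_loss / n
    }
  })
  state$params <- params
  class(state) <- "re_classifier"
  state
}

#' @export
print.re_classifier <- function(x, ...) {
  cat(sprintf("<re_classifier: %d layer(s), width %d, vocab %d>\n",
              x$config$num_layers, x$config$hidden_dim,
              length(x$tokenizer$vocab)))
  invisible(x)
}

#' Predict relation-label distributions
#'
#' @param object a trained (or freshly initialized) `re_classifier`.
#' @param examples an [re_examples()] data.frame (any number of rows).
#' @param ... unused.
#' @return numeric matrix, one row per example, columns the six relation
#'   labels; each row is a normalized confidence distribution (non-negative,
#'   summing to 1). The predicted label is the per-row argmax (see
#'   [predict_labels()]).
#' @export
predict.re_classifier <- function(object, examples, ...) {
  out <- matrix(NA_real_, nrow(examples), length(object$labels),
                dimnames = list(NULL, object$labels))
  for (i in seq_len(nrow(examples))) {
    pr <- tokenize_pair(example = examples[i, , drop = FALSE],
                        tokenizer = object$tokenizer, config = object$config)
    fw <- encoder_forward(object$params, object$config, pr$ids, pr$segment)
    out[i, ] <- classify_forward(object$params, fw$H_out)$probs
  }
  out
}

#' @rdname predict.re_classifier
#' @param state a trained `re_classifier`.
#' @export
predict_labels <- function(state, examples) {
  probs <- predict(state, examples)
  state$labels[max.col(probs, ties.method = "first")]
}

mean_batch_loss <- function(state, examples, weights = NULL) {
  w <- weights %||% stats::setNames(rep(1, 6L), ALL_RELATIONS)
  probs <- predict(state, examples)
  y <- match(examples$label, state$labels)
  mean(vapply(seq_len(nrow(examples)), function(i) {
    -w[[examples$label[i]]] * log(max(probs[i, y[i]], 1e-12))
  }, 0))
}

#' Domain fine-tuning by masked-language modelling
#'
#' Self-supervised fine-tuning on raw abstracts: a fraction of each
#' sequence's tokens is replaced by the mask token and the encoder is
#' trained to recover them (cross-entropy over the vocabulary at the masked
#' positions). The returned checkpoint plugs into [train_classifier()] to
#' seed the downstream relation task with domain text. Held-out masked-token
#' loss before and after training is recorded; with nonzero steps it should
#' decrease.
#'
#' @param corpus non-empty list of `annotated_document` objects.
#' @param enc an [encoder_config()].
#' @param mask_fraction fraction of tokens masked per sequence (>=1 token).
#' @param steps number of minibatch updates; 0 leaves the checkpoint
#'   unchanged.
#' @param seed integer RNG seed.
#' @param learning_rate,batch_size,optimizer optimization settings.
#' @param holdout_frac fraction of documents held out for the loss check.
#' @param checkpoint optional starting checkpoint (tokenizer + params).
#' @return object of class `mlm_checkpoint`: list with `tokenizer`,
#'   `params`, `config`, `loss_before`, `loss_after`.
#' @export
domain_finetune_mlm <- function(corpus, enc, mask_fraction = 0.15,
                                steps = 100L, seed = 1L,
                                learning_rate = 1e-3, batch_size = 8L,
                                optimizer = "adam", holdout_frac = 0.1,
                                checkpoint = NULL) {
  stopifnot(length(corpus) >= 1L, mask_fraction > 0, mask_fraction <= 1)
  texts <- vapply(corpus, doc_text, "")
  if (is.null(checkpoint)) {
    tokenizer <- build_tokenizer(texts)
    params <- init_params(enc, length(tokenizer$vocab), seed = seed)
  } else {
    tokenizer <- checkpoint$tokenizer
    params <- checkpoint$params
  }
  seqs <- lapply(texts, function(tx) {
    ids <- encode_tokens(tokenizer, tokenize_text(tx))
    head(ids, enc$max_seq_len)
  })
  seqs <- seqs[lengths(seqs) >= 2L]
  stopifnot(length(seqs) >= 2L)
  n_hold <- max(1L, floor(length(seqs) * holdout_frac))
  hold <- seqs[seq_len(n_hold)]                 # deterministic head slice
  tr <- seqs[-seq_len(n_hold)]
  if (!length(tr)) tr <- hold
  mask_id <- tokenizer$index[[MASK_TOKEN]]
  mask_plan <- function(ids) {
    k <- max(1L, floor(length(ids) * mask_fraction))
    sort(sample.int(length(ids), k))
  }
  mlm_pass <- function(params, ids, pos, grads = NULL) {
    masked <- ids
    masked[pos] <- mask_id
    fw <- encoder_forward(params, enc, masked, rep(1L, length(ids)))
    Hm <- fw$H_out[pos, , drop = FALSE]
    logits <- add_bias(Hm %*% params$Wm, params$bm)
    probs <- softmax_rows(logits)
    loss <- -mean(log(pmax(probs[cbind(seq_along(pos), ids[pos])], 1e-12)))
    if (is.null(grads)) return(list(loss = loss))
    dlog <- probs
    dlog[cbind(seq_along(pos), ids[pos])] <-
      dlog[cbind(seq_along(pos), ids[pos])] - 1
    dlog <- dlog / length(pos)
    grads$Wm <- grads$Wm + crossprod(Hm, dlog)
    grads$bm <- grads$bm + colSums(dlog)
    dH <- matrix(0, length(ids), enc$hidden_dim)
    dH[pos, ] <- dlog %*% t(params$Wm)
    grads <- encoder_backward(params, enc, fw$cache, dH, grads)
    list(loss = loss, grads = grads)
  }
  holdout_loss <- function(params) {
    with_seed(seed + 1L, {
      mean(vapply(hold, function(ids) {
        mlm_pass(params, ids, mask_plan(ids))$loss
      }, 0))
    })
  }
  loss_before <- holdout_loss(params)
  if (steps > 0L) {
    opt <- make_optimizer(optimizer, learning_rate, params)
    with_seed(seed, {
      for (s in seq_len(steps)) {
        batch <- sample.int(length(tr), min(batch_size, length(tr)))
        grads <- zero_like(params)
        for (i in batch) {
          res <- mlm_pass(params, tr[[i]], mask_plan(tr[[i]]), grads)
          grads <- res$grads
        }
        grads <- lapply(grads, function(g) g / length(batch))
        params <- opt(params, grads)
      }
    })
  }
  structure(list(tokenizer = tokenizer, params = params, config = enc,
                 loss_before = loss_before,
                 loss_after = holdout_loss(params)),
            class = "mlm_checkpoint")
}

#' @export
print.mlm_checkpoint <- function(x, ...) {
  cat(sprintf("<mlm_checkpoint: vocab %d, held-out loss %.4f -> %.4f>\n",
              length(x$tokenizer$vocab), x$loss_before, x$loss_after))
  invisible(x)
}

#' Enumerate a hyperparameter grid
#'
#' Defaults are the published tuning ranges: five epoch values, five
#' learning rates, two losses and three optimizers — 150 grid points.
#'
#' @param epochs,learning_rate,loss,optimizer vectors of candidate values.
#' @return data.frame with one row per configuration.
#' @export
grid_configs <- function(epochs = c(1L, 3L, 5L, 7L, 9L),
                         learning_rate = c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2),
                         loss = c("cross_entropy", "weighted_cross_entropy"),
                         optimizer = c("sgd", "adam", "momentum")) {
  expand.grid(epochs = epochs, learning_rate = learning_rate, loss = loss,
              optimizer = optimizer, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

#' @rdname grid_configs
#' @param path YAML file with keys `epochs`, `learning_rate`, `loss`,
#'   `optimizer`.
#' @export
read_grid_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  do.call(grid_configs, spec[intersect(names(spec),
                                       c("epochs", "learning_rate", "loss",
                                         "optimizer"))])
}

#' Exhaustive grid search
#'
#' Trains one classifier per grid point and ranks configurations by macro-F1
#' on the evaluation set, best first; ties are broken by fewer epochs, then
#' lower learning rate. The evaluation set should normally be a held-out
#' validation split; evaluating on the test set is possible but leaks the
#' test distribution into model selection.
#'
#' @param train,eval_set [re_examples()] data.frames.
#' @param enc an [encoder_config()].
#' @param grid data.frame from [grid_configs()].
#' @param seed,batch_size passed to each [train_config()].
#' @return list with `results` (ranked data.frame with a `macro_f1` column)
#'   and `best` (the best configuration's trained `re_classifier`).
#' @export
grid_search <- function(train, eval_set, enc, grid = grid_configs(),
                        seed = 1L, batch_size = 8L) {
  stopifnot(nrow(grid) >= 1L)
  f1 <- numeric(nrow(grid))
  states <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tc <- train_config(epochs = grid$epochs[i],
                       learning_rate = grid$learning_rate[i],
                       loss = grid$loss[i], optimizer = grid$optimizer[i],
                       seed = seed, batch_size = batch_size)
    st <- train_classifier(train, enc, tc)
    pred <- predict_labels(st, eval_set)
    cm <- confusion_matrix(eval_set$label, pred)
    f1[i] <- class_metrics(cm)$summary$macro_f1
    states[[i]] <- st
  }
  ord <- order(-f1, grid$epochs, grid$learning_rate)
  results <- cbind(grid[ord, , drop = FALSE], macro_f1 = f1[ord])
  rownames(results) <- NULL
  list(results = results, best = states[[ord[1L]]])
}
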
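#' Transformer encoder configuration
#'
#' The relation classifier is a BERT-style encoder: token + segment +
#' position embeddings feed a stack of transformer encoder layers
#' (multi-head self-attention, GELU feed-forward, residual connections with
#' post-layer normalization); the final hidden states are mean-pooled into a
#' dense + softmax classification head over the six relation labels.
#'
#' @param num_layers number of encoder layers.
#' @param num_heads attention heads per layer (`hidden_dim` must divide).
#' @param hidden_dim embedding/hidden width.
#' @param max_seq_len token budget (>= 8).
#' @param ff_dim feed-forward inner width (default `4 * hidden_dim`).
#' @param vocab_size optional fixed tokenizer vocabulary size (otherwise
#'   taken from the tokenizer at training time).
#' @param pretrained_checkpoint optional external checkpoint (e.g. from
#'   [domain_finetune_mlm()]) whose weights and tokenizer seed training.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(num_layers = 12L, num_heads = 12L,
                           hidden_dim = 768L, max_seq_len = 512L,
                           ff_dim = 4L * hidden_dim, vocab_size = NULL,
                           pretrained_checkpoint = NULL) {
  stopifnot(hidden_dim %% num_heads == 0L, max_seq_len >= 8L,
            num_layers >= 1L)
  structure(list(num_layers = as.integer(num_layers),
                 num_heads = as.integer(num_heads),
                 hidden_dim = as.integer(hidden_dim),
                 max_seq_len = as.integer(max_seq_len),
                 ff_dim = as.integer(ff_dim),
                 vocab_size = vocab_size,
                 pretrained_checkpoint = pretrained_checkpoint),
            class = "encoder_config")
}

#' @rdname encoder_config
#' @param preset `"tiny"` (2 layers, 2 heads, width 32 — desk-scale training
#'   from scratch) or `"base"` (12 layers, 12 heads, width 768, budget 512 —
#'   the shape used with external pretrained checkpoints).
#' @export
encoder_preset <- function(preset = c("tiny", "base")) {
  switch(match.arg(preset),
         tiny = encoder_config(num_layers = 2L, num_heads = 2L,
                               hidden_dim = 32L, max_seq_len = 64L),
         base = encoder_config(num_layers = 12L, num_heads = 12L,
                               hidden_dim = 768L, max_seq_len = 512L))
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf("<encoder_config: %d layer(s) x %d head(s), width %d, budget %d>\n",
              x$num_layers, x$num_heads, x$hidden_dim, x$max_seq_len))
  invisible(x)
}

# flat named list of parameter arrays
init_params <- function(config, vocab_size, n_classes = 6L, seed = 1L) {
  H <- config$hidden_dim
  Fd <- config$ff_dim
  L <- config$max_seq_len
  with_seed(seed, {
    rn <- function(r, c) matrix(rnorm(r * c, sd = 0.02), r, c)
    p <- list(emb_tok = rn(vocab_size, H),
              emb_seg = rn(2L, H),
              emb_pos = rn(L, H))
    for (l in seq_len(config$num_layers)) {
      nm <- function(s) paste0("L", l, ".", s)
      p[[nm("Wq")]] <- rn(H, H); p[[nm("bq")]] <- numeric(H)
      p[[nm("Wk")]] <- rn(H, H); p[[nm("bk")]] <- numeric(H)
      p[[nm("Wv")]] <- rn(H, H); p[[nm("bv")]] <- numeric(H)
      p[[nm("Wo")]] <- rn(H, H); p[[nm("bo")]] <- numeric(H)
      p[[nm("g1")]] <- rep(1, H); p[[nm("b1")]] <- numeric(H)
      p[[nm("W1")]] <- rn(H, Fd); p[[nm("bf1")]] <- numeric(Fd)
      p[[nm("W2")]] <- rn(Fd, H); p[[nm("bf2")]] <- numeric(H)
      p[[nm("g2")]] <- rep(1, H); p[[nm("b2")]] <- numeric(H)
    }
    p$Wc <- rn(H, n_classes); p$bc <- numeric(n_classes)
    p$Wm <- rn(H, vocab_size); p$bm <- numeric(vocab_size)
    p
  })
}

zero_like <- function(params) lapply(params, function(x) x * 0)

LN_EPS <- 1e-5

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * invstd
  list(y = sweep(xhat, 2L, g, "*") + matrix(b, nrow(x), ncol(x), byrow = TRUE),
       xhat = xhat, invstd = invstd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- sweep(dy, 2L, g, "*")
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * xhat)
  dx <- cache$invstd * (dxh - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

add_bias <- function(x, b) sweep(x, 2L, b, "+")

# forward pass for one sequence; returns final hidden states and a cache
# sufficient for backprop
encoder_forward <- function(params, config, ids, seg) {
  n <- length(ids)
  X <- params$emb_tok[ids, , drop = FALSE] +
       params$emb_seg[seg, , drop = FALSE] +
       params$emb_pos[seq_len(n), , drop = FALSE]
  H <- config$hidden_dim
  nh <- config$num_heads
  dh <- H %/% nh
  cache <- list(ids = ids, seg = seg, layers = vector("list", config$num_layers))
  for (l in seq_len(config$num_layers)) {
    nm <- function(s) paste0("L", l, ".", s)
    Q <- add_bias(X %*% params[[nm("Wq")]], params[[nm("bq")]])
    K <- add_bias(X %*% params[[nm("Wk")]], params[[nm("bk")]])
    V <- add_bias(X %*% params[[nm("Wv")]], params[[nm("bv")]])
    O <- matrix(0, n, H)
    Ps <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
      P <- softmax_rows(S)
      Ps[[h]] <- P
      O[, cols] <- P %*% V[, cols, drop = FALSE]
    }
    M <- add_bias(O %*% params[[nm("Wo")]], params[[nm("bo")]])
    ln1 <- layernorm_fwd(X + M, params[[nm("g1")]], params[[nm("b1")]])
    X1 <- ln1$y
    Fpre <- add_bias(X1 %*% params[[nm("W1")]], params[[nm("bf1")]])
    Fact <- gelu(Fpre)
    FF <- add_bias(Fact %*% params[[nm("W2")]], params[[nm("bf2")]])
    ln2 <- layernorm_fwd(X1 + FF, params[[nm("g2")]], params[[nm("b2")]])
    cache$layers[[l]] <- list(X = X, Q = Q, K = K, V = V, P = Ps, O = O,
                              ln1 = ln1, X1 = X1, Fpre = Fpre, Fact = Fact)
    X <- ln2$y
    cache$layers[[l]]$ln2 <- ln2
  }
  list(H_out = X, cache = cache)
}

# backward pass; dX2 is the gradient w.r.t. the final hidden states.
# grads is an environment-backed accumulator (flat named list).
encoder_backward <- function(params, config, cache, dX2, grads) {
  nh <- config$num_heads
  H <- config$hidden_dim
  dh <- H %/% nh
  acc <- function(name, g) grads[[name]] <<- grads[[name]] + g
  dX <- dX2
  for (l in rev(seq_len(config$num_layers))) {
    nm <- function(s) paste0("L", l, ".", s)
    cl <- cache$layers[[l]]
    bb <- layernorm_bwd(dX, cl$ln2, params[[nm("g2")]])
    acc(nm("g2"), bb$dg); acc(nm("b2"), bb$db)
    dAdd2 <- bb$dx                       # gradient of X1 + FF
    # feed-forward branch
    dFF <- dAdd2
    acc(nm("bf2"), colSums(dFF))
    acc(nm("W2"), crossprod(cl$Fact, dFF))
    dFact <- dFF %*% t(params[[nm("W2")]])
    dFpre <- dFact * gelu_grad(cl$Fpre)
    acc(nm("bf1"), colSums(dFpre))
    acc(nm("W1"), crossprod(cl$X1, dFpre))
    dX1 <- dAdd2 + dFpre %*% t(params[[nm("W1")]])
    bb <- layernorm_bwd(dX1, cl$ln1, params[[nm("g1")]])
    acc(nm("g1"), bb$dg); acc(nm("b1"), bb$db)
    dAdd1 <- bb$dx                       # gradient of X + M
    # attention output projection
    dM <- dAdd1
    acc(nm("bo"), colSums(dM))
    acc(nm("Wo"), crossprod(cl$O, dM))
    dO <- dM %*% t(params[[nm("Wo")]])
    dQ <- matrix(0, nrow(dO), H)
    dK <- matrix(0, nrow(dO), H)
    dV <- matrix(0, nrow(dO), H)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      P <- cl$P[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dP <- tcrossprod(dOh, cl$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dQ[, cols] <- dS %*% cl$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, cl$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    acc(nm("bq"), colSums(dQ)); acc(nm("Wq"), crossprod(cl$X, dQ))
    acc(nm("bk"), colSums(dK)); acc(nm("Wk"), crossprod(cl$X, dK))
    acc(nm("bv"), colSums(dV)); acc(nm("Wv"), crossprod(cl$X, dV))
    dX <- dAdd1 + dQ %*% t(params[[nm("Wq")]]) +
                  dK %*% t(params[[nm("Wk")]]) +
                  dV %*% t(params[[nm("Wv")]])
  }
  # embedding gradients
  ids <- cache$ids
  seg <- cache$seg
  for (i in seq_along(ids)) {
    grads$emb_tok[ids[i], ] <- grads$emb_tok[ids[i], ] + dX[i, ]
    grads$emb_seg[seg[i], ] <- grads$emb_seg[seg[i], ] + dX[i, ]
    grads$emb_pos[i, ] <- grads$emb_pos[i, ] + dX[i, ]
  }
  grads
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# classification head forward for one encoded sequence
classify_forward <- function(params, H_out) {
  h <- colMeans(H_out)
  logits <- drop(h %*% params$Wc) + params$bc
  list(h = h, probs = softmax_vec(logits))
}
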
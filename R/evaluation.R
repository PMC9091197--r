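METRIC_LABELS <- c("CAG", "HHC", "HTD", "CAD", "GID", "Neg")

#' Six-class confusion matrix
#'
#' Rows are gold labels, columns predicted labels, in the fixed report order
#' CAG, HHC, HTD, CAD, GID, Neg.
#'
#' @param gold,pred equal-length character vectors of labels from the
#'   six-class set.
#' @return 6x6 integer matrix of class `confusion_matrix6`.
#' @export
confusion_matrix <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and pred must have equal length")
  }
  bad <- setdiff(unique(c(gold, pred)), METRIC_LABELS)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(gold, levels = METRIC_LABELS),
              factor(pred, levels = METRIC_LABELS))
  cm <- unclass(matrix(as.integer(cm), 6L, 6L,
                       dimnames = list(gold = METRIC_LABELS,
                                       pred = METRIC_LABELS)))
  class(cm) <- c("confusion_matrix6", class(cm))
  cm
}

#' @rdname confusion_matrix
#' @param m a 6x6 count matrix already in report order (rows gold, columns
#'   predicted), e.g. transcribed from a published report.
#' @export
as_confusion_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == 6L), all(m >= 0))
  dimnames(m) <- list(gold = METRIC_LABELS, pred = METRIC_LABELS)
  storage.mode(m) <- "integer"
  class(m) <- c("confusion_matrix6", class(m))
  m
}

#' Per-class and macro metrics from a confusion matrix
#'
#' Per class k: `TP` is the diagonal entry, `FP` the column sum minus TP,
#' `FN` the row sum minus TP. Two TN conventions are available: the
#' multiclass report convention `tn = "trace"` counts only correctly
#' classified instances of the other classes (`TN_k = trace - TP_k`), which
#' is how published herb relation-extraction reports tabulate TN; the
#' standard one-vs-rest convention `tn = "standard"` counts all instances
#' that are neither gold nor predicted k. Precision, recall and F1 are
#' percentages (`P = TP/(TP+FP) * 100`, `R = TP/(TP+FN) * 100`,
#' `F1 = 2PR/(P+R)`), kept at full precision; the summary row gives summed
#' counts and unweighted macro means. An undefined precision (TP+FP = 0) is
#' reported as 0 and flagged in `precision_defined`.
#'
#' @param cm a [confusion_matrix()].
#' @param tn TN convention, `"trace"` (default) or `"standard"`.
#' @return list of class `class_metrics` with `per_class` (data.frame) and
#'   `summary` (list with summed counts and `macro_precision`,
#'   `macro_recall`, `macro_f1`).
#' @export
class_metrics <- function(cm, tn = c("trace", "standard")) {
  tn <- match.arg(tn)
  stopifnot(inherits(cm, "confusion_matrix6"))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tnv <- if (tn == "trace") sum(tp) - tp else sum(cm) - tp - fp - fn
  p_def <- (tp + fp) > 0L
  prec <- ifelse(p_def, 100 * tp / (tp + fp), 0)
  r_def <- (tp + fn) > 0L
  rec <- ifelse(r_def, 100 * tp / (tp + fn), 0)
  f_def <- (prec + rec) > 0
  f1 <- ifelse(f_def, 2 * prec * rec / (prec + rec), 0)
  per <- data.frame(class = METRIC_LABELS, TP = as.integer(tp),
                    FP = as.integer(fp), FN = as.integer(fn),
                    TN = as.integer(tnv), precision = prec, recall = rec,
                    f1 = f1, precision_defined = p_def,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_class = per,
                 summary = list(TP = sum(tp), FP = sum(fp), FN = sum(fn),
                                TN = sum(tnv),
                                macro_precision = mean(prec),
                                macro_recall = mean(rec),
                                macro_f1 = mean(f1))),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  print(format_metrics_table(x))
  invisible(x)
}

#' Render metrics in the published report layout
#'
#' Rows TP/FP/FN/TN and Pre/Rec/F1 (percentages rounded half-up to one
#' decimal), one column per class plus the Total column (summed counts,
#' unweighted macro means).
#'
#' @param x a [class_metrics()] result (or a `confusion_matrix6`).
#' @return character data.frame mirroring the report layout.
#' @export
format_metrics_table <- function(x) {
  if (inherits(x, "confusion_matrix6")) x <- class_metrics(x)
  per <- x$per_class
  s <- x$summary
  pct <- function(v) sprintf("%.1f%%", round_half_up(v, 1))
  out <- rbind(TP = c(per$TP, s$TP), FP = c(per$FP, s$FP),
               FN = c(per$FN, s$FN), TN = c(per$TN, s$TN),
               Pre = c(pct(per$precision), pct(s$macro_precision)),
               Rec = c(pct(per$recall), pct(s$macro_recall)),
               F1 = c(pct(per$f1), pct(s$macro_f1)))
  colnames(out) <- c(METRIC_LABELS, "Total")
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Precision-recall curve and average precision
#'
#' Examples are ranked by descending confidence; at each rank n the
#' precision P_n and recall R_n over the top-n examples define the step-sum
#' average precision `AP = sum_n (R_n - R_{n-1}) P_n`, the weighted mean of
#' precisions with recall increments as weights.
#'
#' @param scores per-example confidence for the positive class.
#' @param gold binary gold labels (logical or 0/1); at least one positive.
#' @return object of class `pr_curve`: list with `recall`, `precision`
#'   (per-rank vectors) and `ap`.
#' @export
average_precision <- function(scores, gold) {
  gold <- as.integer(as.logical(gold))
  stopifnot(length(scores) == length(gold))
  npos <- sum(gold)
  if (npos == 0L) stop("average precision undefined without positives")
  ord <- order(scores, decreasing = TRUE)
  g <- gold[ord]
  tp <- cumsum(g)
  prec <- tp / seq_along(g)
  rec <- tp / npos
  ap <- sum(diff(c(0, rec)) * prec)
  structure(list(recall = rec, precision = prec, ap = ap),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve: %d point(s), AP = %.4f>\n", length(x$recall), x$ap))
  invisible(x)
}

#' Multi-class average precision
#'
#' @param scores matrix of per-class confidences (columns named by label).
#' @param gold character vector of gold labels.
#' @param average `"macro"` (unweighted mean of one-vs-rest APs over labels
#'   present in the gold) or `"micro"` (all label-example pairs pooled).
#' @return numeric scalar.
#' @export
multiclass_ap <- function(scores, gold, average = c("macro", "micro")) {
  average <- match.arg(average)
  labs <- intersect(colnames(scores), unique(gold))
  if (average == "macro") {
    mean(vapply(labs, function(l) {
      average_precision(scores[, l], gold == l)$ap
    }, 0))
  } else {
    sc <- as.vector(scores[, labs])
    gd <- as.vector(vapply(labs, function(l) gold == l,
                           logical(length(gold))))
    average_precision(sc, gd)$ap
  }
}

#' Occlusion-based token importance
#'
#' For an example whose sentence A contains a sentence with both entity
#' surface forms, the first such sentence is scored by the classifier to
#' obtain `c_star`, the confidence of the gold label. Each token in turn is
#' replaced by a reserved, never-trained occlusion token and the sentence is
#' re-scored, giving `c_i`; the importance of token i is the confidence drop
#' `d_i = c_star - c_i`. Large drops mark entity tokens and the cue words
#' that semantically determine the relation.
#'
#' @param state a trained `re_classifier`.
#' @param example one-row [re_examples()] data.frame.
#' @param gold_label gold relation label (defaults to `example$label`).
#' @param occlusion_token replacement token (default the reserved `[occ]`).
#' @return object of class `token_importance`: list with `sentence`,
#'   `tokens`, `c_star`, `c` and `d` (one score per token).
#' @export
token_importance <- function(state, example, gold_label = example$label,
                             occlusion_token = OCC_TOKEN) {
  stopifnot(inherits(state, "re_classifier"), nrow(example) == 1L)
  sents <- split_sentences(example$sentence_a)
  has_both <- grepl(example$head_text, sents$sentence, fixed = TRUE) &
              grepl(example$tail_text, sents$sentence, fixed = TRUE)
  if (!any(has_both)) {
    stop("no evidence sentence: sentence A has no sentence containing both entities")
  }
  sentence <- sents$sentence[which(has_both)[1L]]
  tokens <- tokenize_text(sentence)
  gi <- match(gold_label, state$labels)
  score <- function(toks) {
    ex <- example
    ex$sentence_a <- paste(toks, collapse = " ")
    predict(state, ex)[1L, gi]
  }
  c_star <- score(tokens)
  c_i <- vapply(seq_along(tokens), function(i) {
    toks <- tokens
    toks[i] <- occlusion_token
    score(toks)
  }, 0)
  structure(list(sentence = sentence, tokens = tokens, c_star = c_star,
                 c = c_i, d = c_star - c_i),
            class = "token_importance")
}

#' @export
print.token_importance <- function(x, ...) {
  cat(sprintf("<token_importance: c* = %.4f>\n", x$c_star))
  print(stats::setNames(round(x$d, 4), x$tokens))
  invisible(x)
}

#' Read and write prediction files
#'
#' TSV with columns: example id, gold label, predicted label, then the six
#' per-class confidence scores in report order.
#'
#' @param ids example identifiers.
#' @param gold gold labels.
#' @param scores matrix of per-class confidences (columns in
#'   `CAG, HHC, HTD, CAD, GID, Neg` order or named).
#' @param path file path.
#' @return `write_predictions` returns `path` invisibly;
#'   `read_predictions` returns a data.frame.
#' @export
write_predictions <- function(ids, gold, scores, path) {
  if (!is.null(colnames(scores))) {
    scores <- scores[, METRIC_LABELS, drop = FALSE]
  }
  pred <- METRIC_LABELS[max.col(scores, ties.method = "first")]
  df <- data.frame(id = ids, gold = gold, pred = pred, scores,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", "gold", "pred", METRIC_LABELS)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
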
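#' One-vs-rest confusion counts per class
#'
#' For each class c, treating c as positive and all other classes as
#' negative: TP (true c predicted c), FP (other predicted c), FN (true c
#' predicted other), TN (the rest). For every class TP+FP+FN+TN = N, and the
#' TP counts summed over classes equal the number of correct predictions.
#'
#' @param y_true integer vector of true class indices in `[0, C)`.
#' @param y_pred integer vector of predicted class indices, same length.
#' @param n_classes number of classes C; default `max(index) + 1`.
#' @return data frame with one row per class: `class`, `TP`, `FP`, `FN`,
#'   `TN`, `support` (true count of the class).
#' @export
confusion_counts <- function(y_true, y_pred, n_classes = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  if (length(y_true) == 0L) stop("empty input")
  if (is.null(n_classes)) n_classes <- max(y_true, y_pred) + 1L
  if (any(y_true < 0 | y_true >= n_classes) || any(y_pred < 0 | y_pred >= n_classes)) {
    stop("label out of range [0, C)")
  }
  n <- length(y_true)
  tab <- table(factor(y_true, levels = 0:(n_classes - 1L)),
               factor(y_pred, levels = 0:(n_classes - 1L)))
  tp <- diag(tab)
  fp <- colSums(tab) - tp
  fn <- rowSums(tab) - tp
  data.frame(class = 0:(n_classes - 1L),
             TP = as.integer(tp), FP = as.integer(fp), FN = as.integer(fn),
             TN = as.integer(n - tp - fp - fn),
             support = as.integer(rowSums(tab)))
}

#' Per-class precision, recall and F1 from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = TP/(TP + 0.5 (FN+FP)).
#' The F1 form is algebraically 2PR/(P+R) whenever P+R > 0. Degenerate 0/0
#' ratios (a class absent from both truth and predictions) return 0 with a
#' warning rather than NaN: in problems with dozens of classes empty
#' predicted classes are routine, and NaNs would poison fitness evaluation.
#'
#' @param counts output of [confusion_counts()], or any data frame with
#'   `TP`, `FP`, `FN` columns.
#' @param warn emit a warning on degenerate 0/0 classes (default `TRUE`).
#' @return data frame with `class`, `precision`, `recall`, `f1`, `support`.
#' @export
class_metrics <- function(counts, warn = TRUE) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  degenerate <- (tp + fp == 0) | (tp + fn == 0) | (tp + 0.5 * (fn + fp) == 0)
  if (warn && any(degenerate)) {
    warning(sprintf("%d class(es) with degenerate 0/0 metric set to 0", sum(degenerate)))
  }
  data.frame(class = counts$class,
             precision = safe_div(tp, tp + fp),
             recall = safe_div(tp, tp + fn),
             f1 = safe_div(tp, tp + 0.5 * (fn + fp)),
             support = if (!is.null(counts$support)) counts$support else tp + fn)
}

#' Overall multi-class accuracy
#'
#' Fraction of samples with `y_pred == y_true` — the multi-class reading of
#' the binary (TP+TN)/(TP+TN+FP+FN) formula.
#'
#' @inheritParams confusion_counts
#' @return a number in `[0, 1]`.
#' @export
overall_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  if (length(y_true) == 0L) stop("empty input")
  mean(as.integer(y_true) == as.integer(y_pred))
}

#' Aggregate per-class metrics across classes
#'
#' `macro`: unweighted mean over classes. `weighted`: support-weighted mean
#' (makes aggregated recall equal overall accuracy for single-label data).
#' `micro`: metrics of the pooled one-vs-rest counts, which for single-label
#' multi-class input collapse to precision = recall = F1 = accuracy.
#'
#' @param metrics output of [class_metrics()].
#' @param counts output of [confusion_counts()] (needed for `micro`).
#' @param scheme one of `"weighted"`, `"macro"`, `"micro"`.
#' @return named numeric vector `c(precision=, recall=, f1=)`.
#' @export
aggregate_metrics <- function(metrics, counts = NULL,
                              scheme = c("weighted", "macro", "micro")) {
  scheme <- match.arg(scheme)
  if (scheme == "micro") {
    if (is.null(counts)) stop("micro aggregation needs the confusion counts")
    tp <- sum(counts$TP); fp <- sum(counts$FP); fn <- sum(counts$FN)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (tp + 0.5 * (fn + fp) > 0) tp / (tp + 0.5 * (fn + fp)) else 0
    return(c(precision = p, recall = r, f1 = f))
  }
  w <- if (scheme == "weighted") {
    if (sum(metrics$support) == 0) stop("zero total support")
    metrics$support / sum(metrics$support)
  } else {
    rep(1 / nrow(metrics), nrow(metrics))
  }
  c(precision = sum(w * metrics$precision),
    recall = sum(w * metrics$recall),
    f1 = sum(w * metrics$f1))
}

#' Top-k accuracy
#'
#' Fraction of samples whose true class is among the k highest-probability
#' classes. Ranking ties are broken toward the lowest class index, consistent
#' with [predict_classes()], so `top_1` equals argmax accuracy exactly.
#'
#' @param m a `probability_matrix`.
#' @param y_true integer vector of true class indices.
#' @param k number of top classes to consider, `1 <= k <= C`.
#' @return a number in `[0, 1]`.
#' @export
top_k_accuracy <- function(m, y_true, k) {
  m <- unclass(as.matrix(m))
  y_true <- as.integer(y_true)
  if (length(y_true) != nrow(m)) stop("labels do not match matrix rows")
  if (k < 1L || k > ncol(m)) stop("k out of range [1, C]")
  hits <- vapply(seq_len(nrow(m)), function(i) {
    # order(-p) is a stable sort: ties keep ascending class index
    topk <- order(-m[i, ])[seq_len(k)] - 1L
    y_true[i] %in% topk
  }, logical(1L))
  mean(hits)
}

#' Full evaluation of a probability matrix against ground truth
#'
#' Computes overall accuracy, per-class one-vs-rest precision/recall/F1,
#' their micro/macro/weighted aggregates, and top-k accuracy for each
#' requested k.
#'
#' @param m a `probability_matrix` of (typically fused) class probabilities.
#' @param y_true integer vector of true class indices in `[0, C)`.
#' @param ks integer vector of k values for top-k accuracy (default `c(1, 3)`).
#' @param warn passed to [class_metrics()].
#' @return object of class `"evaluation_report"`: list with `accuracy`,
#'   `per_class` (data frame), `aggregated` (3 x 3 matrix, schemes x
#'   metrics), `top_k` (named numeric), `support`, `n`.
#' @export
evaluate_predictions <- function(m, y_true, ks = c(1L, 3L), warn = TRUE) {
  m <- if (inherits(m, "probability_matrix")) m else
    probability_matrix(as.matrix(m))
  y_true <- as.integer(y_true)
  C <- ncol(m)
  if (any(y_true < 0 | y_true >= C)) stop("label out of range [0, C)")
  ks <- sort(unique(as.integer(ks)))
  ks <- ks[ks >= 1L & ks <= C]
  y_pred <- predict_classes(m)
  counts <- confusion_counts(y_true, y_pred, n_classes = C)
  per_class <- class_metrics(counts, warn = warn)
  agg <- rbind(micro = aggregate_metrics(per_class, counts, "micro"),
               macro = aggregate_metrics(per_class, counts, "macro"),
               weighted = aggregate_metrics(per_class, counts, "weighted"))
  topk <- vapply(ks, function(k) top_k_accuracy(m, y_true, k), numeric(1L))
  names(topk) <- paste0("top_", ks)
  out <- list(accuracy = overall_accuracy(y_true, y_pred),
              per_class = per_class, aggregated = agg, top_k = topk,
              support = per_class$support, n = length(y_true))
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat(sprintf("Evaluation over %d samples, %d classes\n", x$n, nrow(x$per_class)))
  cat(sprintf("  accuracy: %.*f\n", digits, x$accuracy))
  cat("  aggregated (precision / recall / f1):\n")
  for (s in rownames(x$aggregated)) {
    cat(sprintf("    %-9s %.*f / %.*f / %.*f\n", s,
                digits, x$aggregated[s, "precision"],
                digits, x$aggregated[s, "recall"],
                digits, x$aggregated[s, "f1"]))
  }
  for (nm in names(x$top_k)) cat(sprintf("  %s accuracy: %.*f\n", nm, digits, x$top_k[[nm]]))
  invisible(x)
}

#' Write an evaluation report as YAML
#'
#' All metrics are serialized at full double precision; reading the file back
#' reproduces the values exactly as printed.
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(
    n_samples = report$n,
    accuracy = report$accuracy,
    aggregated = lapply(rownames(report$aggregated), function(s)
      as.list(report$aggregated[s, ])),
    top_k = as.list(report$top_k),
    per_class = lapply(seq_len(nrow(report$per_class)), function(i)
      as.list(report$per_class[i, ]))
  )
  names(obj$aggregated) <- rownames(report$aggregated)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}
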
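#' Confusion counts for a balanced binary classifier
#'
#' Bookkeeping follows the class-total convention common in site-prediction
#' papers: total positives N+, total negatives N-, false negatives (positives
#' called negative) and false positives (negatives called positive).
#'
#' @param n_pos,n_neg Class totals (each >= 1).
#' @param fn Positives predicted negative, `0 <= fn <= n_pos`.
#' @param fp Negatives predicted positive, `0 <= fp <= n_neg`.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(n_pos, n_neg, fn, fp) {
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  fn <- as.integer(fn); fp <- as.integer(fp)
  if (n_pos < 1L || n_neg < 1L) {
    stop("both classes must be nonempty", call. = FALSE)
  }
  if (fn < 0L || fn > n_pos || fp < 0L || fp > n_neg) {
    stop("fn must be in 0..n_pos and fp in 0..n_neg", call. = FALSE)
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, fn = fn, fp = fp),
            class = "confusion_counts")
}

#' Tally predictions into confusion counts
#'
#' @param labels Character vector of true labels (`"pos"` / `"neg"`) or
#'   logical (TRUE = positive).
#' @param predicted Predicted labels, same encoding.
#' @return A [confusion_counts].
#' @export
tally_predictions <- function(labels, predicted) {
  if (is.logical(labels)) labels <- ifelse(labels, "pos", "neg")
  if (is.logical(predicted)) predicted <- ifelse(predicted, "pos", "neg")
  stopifnot(length(labels) == length(predicted))
  confusion_counts(
    n_pos = sum(labels == "pos"), n_neg = sum(labels == "neg"),
    fn = sum(labels == "pos" & predicted == "neg"),
    fp = sum(labels == "neg" & predicted == "pos")
  )
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Uses the intuitive class-total formulation:
#' `Sen = 1 - FN/N+`, `Spe = 1 - FP/N-`, `Acc = 1 - (FN + FP)/(N+ + N-)`,
#' `MCC = (1 - (FN/N+ + FP/N-)) / sqrt((1 + (FP - FN)/N+) * (1 + (FN - FP)/N-))`,
#' which is algebraically the Matthews correlation coefficient. When the MCC
#' denominator is zero (the classifier predicts a single class for every
#' sample), MCC is reported as 0 with `mcc_degenerate = TRUE`.
#'
#' @param counts A [confusion_counts].
#' @return An object of class `metric_set` with fields `sen`, `spe`, `acc`,
#'   `mcc`, `mcc_degenerate`, and `counts`.
#' @export
chou_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  np <- counts$n_pos; nn <- counts$n_neg
  fn <- counts$fn; fp <- counts$fp
  sen <- 1 - fn / np
  spe <- 1 - fp / nn
  acc <- 1 - (fn + fp) / (np + nn)
  denom_sq <- (1 + (fp - fn) / np) * (1 + (fn - fp) / nn)
  degenerate <- denom_sq <= 0
  mcc <- if (degenerate) 0 else (1 - (fn / np + fp / nn)) / sqrt(denom_sq)
  structure(
    list(sen = sen, spe = spe, acc = acc, mcc = mcc,
         mcc_degenerate = degenerate, auc = NA_real_, counts = counts),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sen %.2f%%  Spe %.2f%%  Acc %.2f%%  MCC %.4f%s\n",
              100 * x$sen, 100 * x$spe, 100 * x$acc, x$mcc,
              if (!is.na(x$auc)) sprintf("  AUC %.4f", x$auc) else ""))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(Sen = x$sen, Spe = x$spe, Acc = x$acc, MCC = x$mcc, AUC = x$auc)
}

#' ROC curve and AUC from decision scores
#'
#' AUC is computed by the midrank (Mann-Whitney) convention, so ties between
#' a positive and a negative score count one half; this equals the
#' trapezoidal area under the empirical ROC curve. The curve itself is
#' returned as (FPR, TPR) points over all distinct score thresholds.
#'
#' @param labels True labels (`"pos"`/`"neg"` or logical).
#' @param scores Finite numeric decision scores, higher = more positive.
#' @return A list with `auc` and `curve` (data.frame of `threshold`, `fpr`,
#'   `tpr`, from (0, 0) to (1, 1)).
#' @export
roc_auc <- function(labels, scores) {
  if (is.logical(labels)) labels <- ifelse(labels, "pos", "neg")
  stopifnot(length(labels) == length(scores))
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  pos <- labels == "pos"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)

  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE)  # last index per distinct threshold
  curve <- data.frame(
    threshold = c(Inf, scores[ord][keep]),
    fpr = c(0, fp[keep] / nn),
    tpr = c(0, tp[keep] / np)
  )
  list(auc = auc, curve = curve)
}

#' Write an evaluation report
#'
#' @param result An evaluation result (from [jackknife()] or
#'   [evaluate_independent()]).
#' @param path Output path.
#' @param format `"tsv"` (metrics row) or `"json"` (full report with counts
#'   and per-sample scores).
#' @return Invisibly, `path`.
#' @export
write_evaluation <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(result$metrics), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(metrics = as.data.frame(result$metrics),
           counts = unclass(result$metrics$counts),
           scores = result$scores, predicted = result$predicted),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
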
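# Pixel payload of a crop/micrograph/array argument.
as_pixels <- function(x) {
  if (inherits(x, "cell_crop")) return(x$pixels)
  if (inherits(x, "micrograph")) return(x$intensity)
  x
}

#' Signal-to-noise-ratio improvement of a denoiser
#'
#' Quantifies denoising performance on a single crop as the difference, in dB,
#' between the output SNR (denoised vs. clean) and the input SNR (noisy vs.
#' clean):
#' \deqn{SNR_{out} = 10 \log_{10} \frac{\sum_i x_i^2}{\sum_i (\hat x_i - x_i)^2},
#'       \quad
#'       SNR_{in} = 10 \log_{10} \frac{\sum_i x_i^2}{\sum_i (\tilde x_i - x_i)^2},
#'       \quad
#'       SNR_{imp} = SNR_{out} - SNR_{in}}
#' where \eqn{x} is the clean signal, \eqn{\tilde x} its noisy version and
#' \eqn{\hat x} the denoised reconstruction. Sums run over all pixels of the
#' crop. A perfect reconstruction (zero residual) yields an infinite output
#' SNR, reported as `Inf` rather than capped.
#'
#' All three inputs must be on the same intensity scale; the report records
#' nothing about the scale itself, so callers should evaluate on the scale the
#' denoiser consumed.
#'
#' @param clean Clean reference crop (numeric matrix/vector or [cell_crop]).
#' @param noisy Noisy input crop, same shape as `clean`.
#' @param denoised Denoiser output, same shape as `clean`.
#' @return A list of class `snr_report` with elements `snr_in`, `snr_out`,
#'   `snr_imp` (dB) and `n_points` (number of pixels).
#' @export
#' @examples
#' rep <- snr_improvement(c(1, 2), c(1, 3), c(1, 2.5))
#' rep$snr_imp  # ~6.02 dB
snr_improvement <- function(clean, noisy, denoised) {
  x  <- as.numeric(as_pixels(clean))
  xt <- as.numeric(as_pixels(noisy))
  xh <- as.numeric(as_pixels(denoised))
  if (length(x) != length(xt) || length(x) != length(xh)) {
    stop("clean, noisy and denoised crops must have the same shape")
  }
  sig <- sum(x^2)
  if (sig == 0) stop("SNR undefined: clean crop is all-zero")
  snr_db <- function(resid2) {
    if (resid2 == 0) Inf else 10 * log10(sig / resid2)
  }
  snr_in  <- snr_db(sum((xt - x)^2))
  snr_out <- snr_db(sum((xh - x)^2))
  structure(
    list(snr_in = snr_in, snr_out = snr_out, snr_imp = snr_out - snr_in,
         n_points = length(x)),
    class = "snr_report"
  )
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SNR_in %.3f dB, SNR_out %.3f dB, improvement %.3f dB (%d points)\n",
              x$snr_in, x$snr_out, x$snr_imp, x$n_points))
  invisible(x)
}

#' One-vs-rest confusion counts
#'
#' Tallies true/false positives and negatives for one class against all
#' others pooled, the convention used for per-class rows of multi-class
#' performance tables.
#'
#' @param truth Vector of true labels.
#' @param predicted Vector of predicted labels, same length.
#' @param positive_class The label treated as positive.
#' @return Named integer vector `c(tp, tn, fp, fn)`; the four counts sum to
#'   `length(truth)`.
#' @export
confusion_counts <- function(truth, predicted, positive_class) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length")
  }
  if (!positive_class %in% c(truth, predicted)) {
    stop("positive_class not present in label universe")
  }
  tp_ <- sum(truth == positive_class & predicted == positive_class)
  tn_ <- sum(truth != positive_class & predicted != positive_class)
  fp_ <- sum(truth != positive_class & predicted == positive_class)
  fn_ <- sum(truth == positive_class & predicted != positive_class)
  c(tp = tp_, tn = tn_, fp = fp_, fn = fn_)
}

#' Derived classification metrics from confusion counts
#'
#' Computes the standard one-vs-rest metric set from (TP, TN, FP, FN):
#' accuracy, precision (= PPV), recall (= sensitivity), specificity, F1 and
#' NPV. A metric whose denominator is zero is reported as `NA` (serialized as
#' null in JSON exports), never coerced to 0.
#'
#' @param counts Named or positional numeric vector `(tp, tn, fp, fn)`.
#' @return List of class `class_metrics` with the four counts and the eight
#'   derived fractions.
#' @export
class_metrics <- function(counts) {
  if (length(counts) != 4 || any(counts < 0)) {
    stop("counts must be four non-negative values (tp, tn, fp, fn)")
  }
  if (!is.null(names(counts)) && all(c("tp", "tn", "fp", "fn") %in% names(counts))) {
    counts <- counts[c("tp", "tn", "fp", "fn")]
  }
  tp <- counts[[1]]; tn <- counts[[2]]; fp <- counts[[3]]; fn <- counts[[4]]
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- frac(tp, tp + fp)
  recall <- frac(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         accuracy = frac(tp + tn, tp + tn + fp + fn),
         precision = precision,
         recall = recall,
         specificity = frac(tn, tn + fp),
         sensitivity = recall,
         f1 = f1,
         ppv = precision,
         npv = frac(tn, tn + fn)),
    class = "class_metrics"
  )
}

#' Per-class metrics table for a multi-class prediction
#'
#' One row per class with one-vs-rest counts and derived metrics, in the
#' column order of standard cytometry performance tables. Fractions are
#' rounded half-even to 4 decimals when `digits` is given.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Class universe; defaults to sorted union of labels.
#' @param digits Decimal places for the derived columns, or `NULL` for full
#'   precision.
#' @return A data.frame with columns class, tp, tn, fp, fn, accuracy,
#'   precision, recall, specificity, sensitivity, f1, ppv, npv.
#' @export
metrics_table <- function(truth, predicted, classes = NULL, digits = 4) {
  if (is.null(classes)) classes <- sort(unique(c(as.character(truth), as.character(predicted))))
  rows <- lapply(classes, function(cl) {
    m <- class_metrics(confusion_counts(truth, predicted, cl))
    vals <- unlist(m[c("accuracy", "precision", "recall", "specificity",
                       "sensitivity", "f1", "ppv", "npv")])
    if (!is.null(digits)) vals <- round(vals, digits)
    data.frame(class = cl, tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
               t(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps all score thresholds and integrates the ROC curve by the trapezoid
#' rule. The AUC equals the probability that a random positive outranks a
#' random negative (ties counted half), so it is invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth Binary truth: logical, or labels compared to `positive_class`.
#' @param positive_class Label counted as positive when `truth` is not logical.
#' @return List with `points` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive_class = NULL) {
  if (!is.logical(truth)) {
    if (is.null(positive_class)) stop("positive_class required for non-logical truth")
    truth <- truth == positive_class
  }
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) stop("AUC undefined: truth contains a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # one ROC point per distinct score value (ties collapse onto one point)
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(y)[last_of_run] / n_pos
  fpr <- cumsum(!y)[last_of_run] / n_neg
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, s[last_of_run]))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}

#' Multi-class one-vs-rest ROC set
#'
#' @param score_matrix Samples x classes matrix of class scores (e.g. softmax
#'   probabilities); column names are the class labels.
#' @param truth True labels.
#' @return Named list per class, each as returned by [roc_auc()].
#' @export
roc_set <- function(score_matrix, truth) {
  classes <- colnames(score_matrix)
  if (is.null(classes)) stop("score_matrix must have class column names")
  out <- lapply(classes, function(cl) roc_auc(score_matrix[, cl], truth, cl))
  names(out) <- classes
  out
}

#' Count comparison between reference and predicted per-class totals
#'
#' Mirrors manual-vs-automated counting comparisons for a heterogeneous
#' sample: per-class absolute and percent difference of predicted counts
#' against a reference count (for synthetic frames, the simulator ground
#' truth).
#'
#' @param truth_counts Named numeric vector of reference counts per class.
#' @param predicted_counts Named numeric vector over the same class universe.
#' @return data.frame with class, truth, predicted, diff, pct_diff.
#' @export
count_report <- function(truth_counts, predicted_counts) {
  classes <- names(truth_counts)
  if (is.null(classes)) {
    classes <- as.character(seq_along(truth_counts))
    names(truth_counts) <- classes
  }
  if (!setequal(classes, names(predicted_counts))) {
    stop("truth and predicted counts must share one class universe")
  }
  pred <- as.numeric(predicted_counts[classes])
  tru <- as.numeric(truth_counts[classes])
  data.frame(class = classes, truth = tru, predicted = pred,
             diff = pred - tru,
             pct_diff = ifelse(tru == 0, NA_real_, 100 * (pred - tru) / tru),
             stringsAsFactors = FALSE)
}

#' Export a per-class metrics table as JSON
#'
#' Nested per-class JSON with undefined metrics serialized as null and
#' infinite values as the string "inf".
#'
#' @param tab data.frame from [metrics_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(tab, path) {
  obj <- lapply(seq_len(nrow(tab)), function(i) {
    row <- as.list(tab[i, setdiff(names(tab), "class")])
    lapply(row, function(v) if (is.numeric(v) && is.infinite(v)) "inf" else v)
  })
  names(obj) <- tab$class
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
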
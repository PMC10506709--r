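check_binary <- function(x, name) {
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    abort(sprintf("`%s` must be binary (0/1) without missing values.", name))
  }
  x
}

#' Confusion-matrix counts
#'
#' @param truth Binary vector of true labels (1 = hotspot).
#' @param estimate Binary vector of predicted labels, same length.
#' @return A one-row tibble with integer columns `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(truth, estimate) {
  truth <- check_binary(truth, "truth")
  estimate <- check_binary(estimate, "estimate")
  if (length(truth) != length(estimate)) {
    abort(sprintf("Length mismatch: %d true labels vs %d predictions",
                  length(truth), length(estimate)))
  }
  if (length(truth) < 1L) abort("Need at least one observation.")
  tibble(
    tp = sum(truth == 1L & estimate == 1L),
    fn = sum(truth == 1L & estimate == 0L),
    fp = sum(truth == 0L & estimate == 1L),
    tn = sum(truth == 0L & estimate == 0L)
  )
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Classification metrics from confusion counts
#'
#' Computes accuracy, recall (sensitivity), precision, F1 (harmonic mean of
#' precision and recall) and specificity `tn / (tn + fp)`. A metric whose
#' denominator is zero is reported as `NA` rather than 0, so degenerate
#' predictions do not silently bias comparisons.
#'
#' @param cm One-row tibble from [confusion_counts()] (columns `tp`, `fn`,
#'   `fp`, `tn`).
#' @return A one-row tibble with columns `accuracy`, `recall`, `precision`,
#'   `f1`, `specificity`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(all(c("tp", "fn", "fp", "tn") %in% names(cm)), nrow(cm) == 1L)
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  total <- tp + fn + fp + tn
  if (total < 1L) abort("Empty confusion matrix.")
  precision <- safe_ratio(tp, tp + fp)
  recall <- safe_ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble(
    accuracy = (tp + tn) / total,
    recall = recall,
    precision = precision,
    f1 = f1,
    specificity = safe_ratio(tn, tn + fp)
  )
}

# F1 at a fixed threshold with NA mapped to 0, for early-stopping comparisons
f1_at_threshold <- function(truth, score, threshold = 0.5) {
  m <- classification_metrics(
    confusion_counts(truth, as.integer(score >= threshold))
  )
  if (is.na(m$f1)) 0 else m$f1
}

#' Receiver operating characteristic curve
#'
#' One point per distinct score value (ties grouped), from (0, 0) to (1, 1),
#' sweeping the decision threshold from above the largest score downwards.
#'
#' @param truth Binary true labels; both classes must be present.
#' @param score Numeric classifier scores (higher = more hotspot-like).
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, ordered by
#'   increasing `fpr`.
#' @export
roc_curve <- function(truth, score) {
  truth <- check_binary(truth, "truth")
  if (length(truth) != length(score)) abort("Length mismatch.")
  if (any(!is.finite(score))) abort("`score` must be finite.")
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC requires both classes in `truth`.")
  }
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- truth[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1L)[last_of_tie]
  fp <- cumsum(y == 0L)[last_of_tie]
  tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of [roc_curve()]; equals the probability that a
#' random positive is scored above a random negative (ties counted half).
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(truth, score) {
  rc <- roc_curve(truth, score)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + rc$tpr[-1]) / 2)
}

#' Evaluate scored predictions against true labels
#'
#' @param truth Binary true labels.
#' @param score Classifier scores in \[0, 1\].
#' @param threshold Decision threshold applied to `score` (default 0.5).
#' @return A one-row tibble: confusion counts, thresholded metrics and
#'   `auc` (AUC is `NA` when only one class is present).
#' @export
evaluate_predictions <- function(truth, score, threshold = 0.5) {
  cm <- confusion_counts(truth, as.integer(score >= threshold))
  auc <- if (sum(truth == 1L) > 0L && sum(truth == 0L) > 0L) {
    roc_auc(truth, score)
  } else {
    NA_real_
  }
  dplyr::bind_cols(cm, classification_metrics(cm), tibble(auc = auc))
}

#' Format metric reports as an aligned text table
#'
#' @param reports A tibble of metric rows (e.g. from
#'   [evaluate_predictions()]); a `set` column, if present, labels the rows.
#' @return Character vector of table lines (header + one line per row).
#' @export
format_metric_table <- function(reports) {
  fmt <- function(x) ifelse(is.na(x), "   NA ", sprintf("%.4f", x))
  labels <- if ("set" %in% names(reports)) reports$set else
    sprintf("row%d", seq_len(nrow(reports)))
  width <- max(nchar(c("Data set", labels)))
  header <- sprintf("%-*s  %6s  %6s  %6s  %6s  %6s", width, "Data set",
                    "Acc", "Recall", "Pre", "F1", "Spe")
  body <- sprintf("%-*s  %s  %s  %s  %s  %s", width, labels,
                  fmt(reports$accuracy), fmt(reports$recall),
                  fmt(reports$precision), fmt(reports$f1),
                  fmt(reports$specificity))
  c(header, body)
}
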
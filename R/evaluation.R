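# Test-set metrics, fold aggregation with t-based confidence intervals, and
# the statistical comparisons used when contrasting classifier variants
# (paired t over folds, 2x2 chi-square contingency, Welch t from summaries).

#' Binary classification metrics
#'
#' Computes the seven evaluation metrics reported for each test set: ROC
#' AUC (Mann-Whitney rank formulation, ties credited 0.5), accuracy,
#' balanced accuracy, and per-class precision and recall. Precision 0 is
#' the negative predictive value, recall 0 the specificity, recall 1 the
#' sensitivity. A precision whose predicted class is empty is undefined
#' and reported as `NA` with the affected class listed in
#' `$undefined` (never silently coerced to 0).
#'
#' @param labels 0/1 vector of reference labels (both classes present).
#' @param scores Predicted probability of class 1, in `[0, 1]`.
#' @param threshold Decision threshold on the class-1 probability
#'   (default 0.5; `scores >= threshold` predicts class 1).
#' @return A `metrics_report` list with fields `auc`, `accuracy`,
#'   `balanced_accuracy`, `precision_0`, `precision_1`, `recall_0`,
#'   `recall_1`, plus `undefined` (character vector) and the confusion
#'   counts `tp`, `tn`, `fp`, `fn`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores),
            all(labels %in% c(0L, 1L)),
            all(scores >= 0 & scores <= 1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present (AUC undefined)")
  r <- rank(scores)                       # midranks handle ties with 0.5 credit
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  undefined <- character(0)
  prec1 <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision_1"); NA_real_
  }
  prec0 <- if (tn + fn > 0) tn / (tn + fn) else {
    undefined <- c(undefined, "precision_0"); NA_real_
  }
  rec1 <- tp / n1; rec0 <- tn / n0
  structure(list(auc = auc,
                 accuracy = (tp + tn) / length(labels),
                 balanced_accuracy = (rec0 + rec1) / 2,
                 precision_0 = prec0, precision_1 = prec1,
                 recall_0 = rec0, recall_1 = rec1,
                 undefined = undefined,
                 tp = tp, tn = tn, fp = fp, fn = fn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- unlist(x[c("auc", "accuracy", "balanced_accuracy",
                  "precision_0", "precision_1", "recall_0", "recall_1")])
  cat("<metrics_report>\n")
  print(round(m, 4))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

.metric_names <- c("auc", "accuracy", "balanced_accuracy",
                   "precision_0", "precision_1", "recall_0", "recall_1")

#' ROC curve points
#'
#' @param labels 0/1 reference labels.
#' @param scores Class-1 probabilities.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, one row per
#'   distinct score plus the two degenerate endpoints.
#' @export
roc_points <- function(labels, scores) {
  labels <- as.integer(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  out <- t(vapply(th, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0L) / sum(labels == 0L),
      tpr = sum(pred & labels == 1L) / sum(labels == 1L))
  }, numeric(2)))
  data.frame(threshold = th, fpr = out[, "fpr"], tpr = out[, "tpr"])
}

.comparison_result <- function(test, statistic, p_value, df,
                               degenerate = FALSE) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 df = df, degenerate = degenerate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, df = %.4g, p = %.4g%s\n",
              x$test, x$statistic, x$df, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Paired t-test on per-fold metric values
#'
#' Two-sided paired t-test, \eqn{t = \bar d / (s_d / \sqrt k)} on
#' \eqn{k - 1} degrees of freedom. If the paired differences have zero
#' variance the test is degenerate: all-zero differences give `p = 1`,
#' a constant nonzero difference is flagged (`degenerate = TRUE`,
#' `p = NA`).
#'
#' @param values_a,values_b Equal-length numeric vectors (k >= 2), e.g. a
#'   metric observed on each cross-validation fold under two models.
#' @return A `comparison_result`.
#' @export
paired_t_test <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  k <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(.comparison_result("paired_t", 0, 1, k - 1))
    return(.comparison_result("paired_t", sign(mean(d)) * Inf, NA_real_,
                              k - 1, degenerate = TRUE))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  .comparison_result("paired_t", unname(ht$statistic), ht$p.value,
                     unname(ht$parameter))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' No continuity correction is applied; df = 1, two-sided p.
#'
#' @param table 2x2 matrix of nonnegative integer counts with all row and
#'   column marginals positive.
#' @return A `comparison_result`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all marginals must be positive")
  ht <- stats::chisq.test(table, correct = FALSE)
  .comparison_result("chi_square_2x2", unname(ht$statistic), ht$p.value,
                     unname(ht$parameter))
}

#' Welch two-sample t-test from summary statistics
#'
#' Computes the Welch statistic and Satterthwaite degrees of freedom from
#' group means, standard deviations and sizes (as printed in a cohort
#' description table), with a two-sided p-value.
#'
#' @param mean1,sd1,n1 Summary of group 1 (`n1 >= 2`, `sd1 > 0`).
#' @param mean2,sd2,n2 Summary of group 2.
#' @return A `comparison_result`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t_stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  .comparison_result("welch_t_summary", t_stat, p, df)
}

#' Aggregate per-fold metrics into means and 95% confidence intervals
#'
#' The interval is \eqn{\bar x \pm t_{0.975, k-1} \, s / \sqrt k} per
#' metric, i.e. a t-based CI for the fold mean.
#'
#' @param reports List of `metrics_report` objects, one per fold (k >= 2).
#' @return A `fold_summary`: data frame with columns `metric`, `mean`,
#'   `ci_low`, `ci_high`, `sd`, plus attribute `per_fold` (k x 7 matrix).
#' @export
summarize_folds <- function(reports) {
  stopifnot(length(reports) >= 2)
  k <- length(reports)
  per_fold <- t(vapply(reports, function(r) unlist(r[.metric_names]),
                       numeric(length(.metric_names))))
  tq <- stats::qt(0.975, df = k - 1)
  means <- colMeans(per_fold)
  sds <- apply(per_fold, 2, stats::sd)
  hw <- tq * sds / sqrt(k)
  out <- data.frame(metric = .metric_names, mean = means,
                    ci_low = means - hw, ci_high = means + hw, sd = sds,
                    row.names = NULL)
  attr(out, "per_fold") <- per_fold
  class(out) <- c("fold_summary", "data.frame")
  out
}
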
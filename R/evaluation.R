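#' Confusion counts for a binary ORI / non-ORI classification
#'
#' Stores the class sizes and the two error counts: `fn`, the number of
#' true ORIs called non-ORI (missed positives), and `fp`, the number of
#' non-ORIs called ORI (false alarms).
#'
#' @param n_pos Number of ORI samples investigated.
#' @param n_neg Number of non-ORI samples investigated.
#' @param fn ORIs predicted non-ORI, `0 <= fn <= n_pos`.
#' @param fp Non-ORIs predicted ORI, `0 <= fp <= n_neg`.
#' @return An object of class `confusion_counts`.
#' @seealso [count_confusion()] to tally from label vectors,
#'   [intuitive_metrics()] for the derived metrics.
#' @export
confusion_counts <- function(n_pos, n_neg, fn, fp) {
  v <- c(n_pos = n_pos, n_neg = n_neg, fn = fn, fp = fp)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (fn > n_pos) stop("fn cannot exceed n_pos")
  if (fp > n_neg) stop("fp cannot exceed n_neg")
  structure(as.list(v), class = "confusion_counts")
}

#' Tally confusion counts from truth and prediction vectors
#'
#' @param truth,predicted Factors or character vectors over
#'   `{"nonORI", "ORI"}` of equal length.
#' @return A [confusion_counts()] object.
#' @export
count_confusion <- function(truth, predicted) {
  truth <- factor(as.character(truth), levels = c("nonORI", "ORI"))
  predicted <- factor(as.character(predicted), levels = c("nonORI", "ORI"))
  stopifnot(length(truth) == length(predicted), !anyNA(truth), !anyNA(predicted))
  confusion_counts(n_pos = sum(truth == "ORI"),
                   n_neg = sum(truth == "nonORI"),
                   fn = sum(truth == "ORI" & predicted == "nonORI"),
                   fp = sum(truth == "nonORI" & predicted == "ORI"))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("ORI: %d (missed %d)   non-ORI: %d (false alarms %d)\n",
              x$n_pos, x$fn, x$n_neg, x$fp))
  invisible(x)
}

#' The four intuitive metrics: Sn, Sp, Acc, MCC
#'
#' Computes sensitivity, specificity, overall accuracy and the Matthews
#' correlation coefficient in their intuitive error-rate form:
#' \deqn{Sn = 1 - fn/N^+,\quad Sp = 1 - fp/N^-,\quad
#'       Acc = 1 - (fn + fp)/(N^+ + N^-),}
#' \deqn{MCC = \frac{1 - (fn/N^+ + fp/N^-)}
#'       {\sqrt{(1 + (fp - fn)/N^+)(1 + (fn - fp)/N^-)}}.}
#' These are algebraically identical to the conventional TP/TN/FP/FN
#' formulas. When a predicted class is empty the conventional MCC
#' denominator vanishes; MCC is then reported as 0 with the
#' `mcc_undefined` flag set.
#'
#' @param counts A [confusion_counts()] object.
#' @param auc Optional AUC to carry in the report.
#' @return An object of class `metrics_report` with fields `Sn`, `Sp`,
#'   `Acc`, `MCC`, `auc`, `counts`, `mcc_undefined`.
#' @export
#' @examples
#' intuitive_metrics(confusion_counts(10, 10, fn = 2, fp = 3))
intuitive_metrics <- function(counts, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  P <- counts$n_pos; N <- counts$n_neg; fn <- counts$fn; fp <- counts$fp
  if (P == 0 || N == 0) stop("both classes must be present (n_pos > 0, n_neg > 0)")
  Sn <- 1 - fn / P
  Sp <- 1 - fp / N
  Acc <- 1 - (fn + fp) / (P + N)
  radicand <- (1 + (fp - fn) / P) * (1 + (fn - fp) / N)
  undefined <- radicand <= 0
  # clamp against floating-point spill a few ulp outside [-1, 1]
  MCC <- if (undefined) 0 else
    min(1, max(-1, (1 - (fn / P + fp / N)) / sqrt(radicand)))
  structure(list(Sn = Sn, Sp = Sp, Acc = Acc, MCC = MCC, auc = auc,
                 counts = counts, mcc_undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("  Sn = %.*f   Sp = %.*f   Acc = %.*f   MCC = %.*f%s",
              digits, x$Sn, digits, x$Sp, digits, x$Acc, digits, x$MCC,
              if (x$mcc_undefined) " (undefined, reported as 0)" else ""))
  if (!is.na(x$auc)) cat(sprintf("   AUC = %.*f", digits, x$auc))
  cat("\n")
  invisible(x)
}

#' Serialize a metrics report as JSON
#'
#' @param report A `metrics_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  x <- list(Sn = report$Sn, Sp = report$Sp, Acc = report$Acc,
            MCC = report$MCC, AUC = report$auc,
            counts = report$counts[c("n_pos", "n_neg", "fn", "fp")],
            mcc_undefined = report$mcc_undefined)
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("package 'jsonlite' is required for JSON output")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' ROC curve and AUC from ranking scores
#'
#' Sweeps the decision threshold over all distinct scores (ties grouped),
#' yielding one (fpr, tpr) point per threshold plus the (0, 0) origin,
#' and integrates the curve by the trapezoid rule. With ties handled by
#' grouping, the trapezoid AUC equals the normalized Mann-Whitney U
#' statistic.
#'
#' @param scores Numeric ranking scores (higher = more ORI-like).
#' @param labels Truth labels over `{"nonORI", "ORI"}`; both classes must
#'   be present.
#' @return An object of class `ori_roc`: list with `curve` (data.frame of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("nonORI", "ORI"))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  P <- sum(labels == "ORI"); N <- sum(labels == "nonORI")
  if (P == 0 || N == 0) stop("both classes must be present to compute a ROC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  pos <- labels[o] == "ORI"
  grp_end <- cumsum(rle(s)$lengths)           # last index of each tie group
  tp <- cumsum(pos)[grp_end]
  fp <- cumsum(!pos)[grp_end]
  curve <- data.frame(threshold = c(Inf, s[grp_end]),
                      fpr = c(0, fp / N), tpr = c(0, tp / P))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc, n_pos = P, n_neg = N),
            class = "ori_roc")
}

#' @export
print.ori_roc <- function(x, ...) {
  cat(sprintf("ROC over %d ORI / %d non-ORI scores: AUC = %.3f (%d points)\n",
              x$n_pos, x$n_neg, x$auc, nrow(x$curve)))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x An `ori_roc` object from [roc_auc()].
#' @param ... Passed to [plot()].
#' @export
plot.ori_roc <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate (1 - Sp)", ylab = "True positive rate (Sn)",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Write ROC curve points as TSV
#'
#' @param roc An `ori_roc` object.
#' @param path Output path; columns `fpr`, `tpr`, `threshold`.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(roc$curve[, c("fpr", "tpr", "threshold")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Encode a labelled dataset once; shared by the CV drivers.
encode_dataset <- function(data, k, lambda, w, table) {
  if (!is_standardized(table)) table <- standardize_table(table)
  X <- pseknc_matrix(data$sequence, k = k, lambda = lambda, w = w, table = table)
  list(X = X, y = check_labels(data$label))
}

cv_report <- function(scores, y, threshold) {
  pred <- classify_score(scores, threshold)
  rep <- intuitive_metrics(count_confusion(y, pred),
                           auc = roc_auc(scores, y)$auc)
  rep$scores <- scores
  rep$labels <- y
  rep
}

#' Jackknife (leave-one-out) cross-validation
#'
#' The rigorous evaluation protocol: each of the n samples is in turn
#' held out, the classifier is trained on the remaining n - 1, and the
#' held-out sample is scored. The n held-out vote fractions are
#' thresholded at 0.5 for the confusion counts and pooled as ranking
#' scores for the ROC/AUC. With a seeded engine the outcome is unique for
#' a given dataset.
#'
#' @param data Labelled dataset (`sequence`, `label` columns).
#' @param k,lambda,w PseKNC encoding parameters.
#' @param table Property table (standardized internally if raw).
#' @param engine Classifier engine from [rf_engine()] (or any list with
#'   compatible `fit`/`score` closures).
#' @param threshold Vote-fraction decision threshold (default 0.5).
#' @return A `metrics_report` with the pooled held-out `scores` and
#'   `labels` attached.
#' @export
#' @examples
#' ds <- synthesize_dataset(6, 100, epsilon = 1, seed = 1)
#' jackknife(ds, k = 1, lambda = 2, w = 0.5)
jackknife <- function(data, k = 4, lambda = 7, w = 0.9,
                      table = default_property_table(), engine = rf_engine(),
                      threshold = 0.5) {
  enc <- encode_dataset(data, k, lambda, w, table)
  X <- enc$X; y <- enc$y
  if (min(table(y)) < 2L) stop("jackknife needs at least 2 samples per class")
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fit <- engine$fit(X[-i, , drop = FALSE], y[-i])
    scores[i] <- engine$score(fit, X[i, , drop = FALSE])
  }
  cv_report(scores, y, threshold)
}

# Seeded stratified fold assignment: balanced within each class.
stratified_folds <- function(y, K, seed) {
  folds <- integer(length(y))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(K), length(idx)))
  }
  folds
}

#' Stratified K-fold cross-validation
#'
#' Faster surrogate for [jackknife()]: samples are assigned to K
#' label-stratified folds by a seeded shuffle, each fold is scored by a
#' model trained on the others, and results are aggregated exactly as in
#' the jackknife.
#'
#' @inheritParams jackknife
#' @param K Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param folds Optional precomputed fold assignment (integer vector in
#'   `1..K`), e.g. to share folds across configurations.
#' @return A `metrics_report` with pooled held-out `scores` and `labels`.
#' @export
kfold <- function(data, K = 10L, k = 4, lambda = 7, w = 0.9,
                  table = default_property_table(), engine = rf_engine(),
                  seed = 1L, threshold = 0.5, folds = NULL) {
  enc <- encode_dataset(data, k, lambda, w, table)
  X <- enc$X; y <- enc$y
  K <- as.integer(K)
  if (is.null(folds)) folds <- stratified_folds(y, K, seed)
  stopifnot(length(folds) == nrow(X))
  scores <- numeric(nrow(X))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    fit <- engine$fit(X[!hold, , drop = FALSE], y[!hold])
    scores[hold] <- engine$score(fit, X[hold, , drop = FALSE])
  }
  cv_report(scores, y, threshold)
}
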
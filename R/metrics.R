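#' Build a confusion matrix
#'
#' Rows are actual classes, columns are predicted classes.
#'
#' @param actual,predicted integer class labels in `1..K`.
#' @param n_classes number of classes `K`; defaults to the largest label
#'   seen.
#' @return A `K x K` integer matrix.
#' @export
confusion_matrix <- function(actual, predicted, n_classes = NULL) {
  actual <- as.integer(actual); predicted <- as.integer(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length", call. = FALSE)
  if (is.null(n_classes)) n_classes <- max(actual, predicted)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(actual = seq_len(n_classes),
                               predicted = seq_len(n_classes)))
  for (i in seq_along(actual))
    cm[actual[i], predicted[i]] <- cm[actual[i], predicted[i]] + 1L
  cm
}

check_cm <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || nrow(cm) < 2L)
    stop("confusion matrix must be K x K with K >= 2", call. = FALSE)
  if (any(cm < 0)) stop("confusion matrix entries must be >= 0",
                        call. = FALSE)
  if (sum(cm) == 0) stop("confusion matrix is all zero", call. = FALSE)
  cm
}

#' Per-class TP/FP/FN/TN counts
#'
#' For class `k`: TP is the diagonal entry, FP the rest of column `k`, FN
#' the rest of row `k`, TN everything else; the four always partition the
#' total.
#'
#' @param cm a `K x K` confusion matrix (rows actual, columns predicted).
#' @param k class index in `1..K`.
#' @return Named numeric vector `c(tp, fp, fn, tn)`.
#' @export
per_class_counts <- function(cm, k) {
  cm <- check_cm(cm)
  stopifnot(k >= 1, k <= nrow(cm))
  tp <- cm[k, k]
  fp <- sum(cm[, k]) - tp
  fn <- sum(cm[k, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Macro-averaged classification metrics
#'
#' Computes, per class, precision (`TP/(TP+FP)`), sensitivity/recall
#' (`TP/(TP+FN)`), specificity (`TN/(TN+FP)`), F1 (harmonic mean of
#' precision and sensitivity) and the per-class Jaccard term
#' `TP/(TP+FP+FN)`, then macro-averages (unweighted mean over classes).
#' Two accuracies are reported: `accuracy` is the macro mean of the
#' per-class Jaccard terms (the literal published definition), and
#' `accuracy_standard` is `trace/total`, the conventional overall accuracy;
#' the two coincide only for perfect classifiers. Per-class terms with a
#' zero denominator contribute 0 to the macro average with a warning. The
#' Gorodkin multiclass MCC is included.
#'
#' @param cm a `K x K` confusion matrix (rows actual, columns predicted).
#' @return A one-row tibble with columns `accuracy`, `accuracy_standard`,
#'   `precision`, `recall`, `specificity`, `f1`, `mcc`.
#' @export
macro_metrics <- function(cm) {
  cm <- check_cm(cm)
  k <- nrow(cm)
  total <- sum(cm)
  safe <- function(num, den, what) {
    out <- numeric(length(num))
    ok <- den > 0
    out[ok] <- num[ok] / den[ok]
    if (any(!ok))
      warning(sprintf("%s undefined for %d class(es); contributing 0",
                      what, sum(!ok)), call. = FALSE)
    out
  }
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  pre <- safe(tp, tp + fp, "precision")
  sn <- safe(tp, tp + fn, "sensitivity")
  sp <- safe(tn, tn + fp, "specificity")
  f1 <- safe(2 * pre * sn, pre + sn, "F1")
  jac <- safe(tp, tp + fp + fn, "accuracy (per-class)")
  tibble::tibble(
    accuracy = mean(jac),
    accuracy_standard = sum(tp) / total,
    precision = mean(pre),
    recall = mean(sn),
    specificity = mean(sp),
    f1 = mean(f1),
    mcc = multiclass_mcc(cm)
  )
}

#' Multiclass Matthews correlation coefficient
#'
#' Gorodkin's generalization:
#' `(c*s - sum(p*t)) / sqrt((s^2 - sum(p^2)) * (s^2 - sum(t^2)))` with `c`
#' the trace, `s` the total, `t` the row (actual) totals and `p` the column
#' (predicted) totals. Equals the Pearson correlation between the one-hot
#' encodings of truth and prediction. Returns 0 when either variance factor
#' vanishes.
#'
#' @param cm a `K x K` confusion matrix.
#' @return A scalar in `[-1, 1]`.
#' @export
multiclass_mcc <- function(cm) {
  cm <- check_cm(cm)
  s <- sum(cm)
  c0 <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c0 * s - sum(p_k * t_k)
  den1 <- s^2 - sum(p_k^2)
  den2 <- s^2 - sum(t_k^2)
  if (den1 <= 0 || den2 <= 0) return(0)
  num / sqrt(den1 * den2)
}

#' One-vs-rest macro AUC
#'
#' For each class `k` with at least one positive and one negative sample,
#' the probability that a positive sample's class-`k` score exceeds a
#' negative's, ties counting 1/2 (Mann-Whitney convention; set
#' `ties = "strict"` for the strict indicator that counts ties as 0).
#' Classes without both a positive and a negative are skipped with a
#' warning; the result is the unweighted mean over the remaining classes.
#'
#' @param scores `N x K` matrix of class scores (higher = more likely).
#' @param labels integer true labels in `1..K` for the rows of `scores`.
#' @param ties `"half"` (default) or `"strict"`.
#' @return The macro-averaged AUC in `[0, 1]`.
#' @export
auc_ovr <- function(scores, labels, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (nrow(scores) != length(labels))
    stop("one row of scores per label required", call. = FALSE)
  k <- ncol(scores)
  aucs <- rep(NA_real_, k)
  for (cls in seq_len(k)) {
    pos <- labels == cls
    n_pos <- sum(pos); n_neg <- sum(!pos)
    if (n_pos == 0L || n_neg == 0L) next
    sc <- scores[, cls]
    if (ties == "half") {
      r <- rank(sc, ties.method = "average")
      aucs[cls] <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    } else {
      aucs[cls] <- mean(outer(sc[pos], sc[!pos], ">"))
    }
  }
  if (all(is.na(aucs)))
    stop("no class has both positive and negative samples", call. = FALSE)
  if (any(is.na(aucs)))
    warning(sprintf("%d class(es) without both positives and negatives %s",
                    sum(is.na(aucs)), "skipped in the AUC average"),
            call. = FALSE)
  mean(aucs, na.rm = TRUE)
}

#' Full metric report for a set of predictions
#'
#' Confusion-matrix metrics via [macro_metrics()] plus, when a score matrix
#' is supplied, the one-vs-rest macro AUC.
#'
#' @param actual,predicted integer labels in `1..K`.
#' @param scores optional `N x K` score matrix for the AUC.
#' @param n_classes number of classes (defaults to largest label seen).
#' @return A one-row tibble (a metric report).
#' @export
evaluate_predictions <- function(actual, predicted, scores = NULL,
                                 n_classes = NULL) {
  cm <- confusion_matrix(actual, predicted, n_classes)
  rep <- macro_metrics(cm)
  rep$auc_ovr <- if (is.null(scores)) NA_real_ else auc_ovr(scores, actual)
  rep
}

#' Read / write a confusion matrix as headered CSV
#'
#' @param cm a confusion matrix.
#' @param path CSV file path.
#' @return `read_confusion_csv()` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(as.matrix(cm)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
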
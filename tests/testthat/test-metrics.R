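test_that("per-class counts partition the table", {
  cm <- diag(c(3, 4, 5))
  expect_equal(per_class_counts(cm, 1), c(tp = 3, fp = 0, fn = 0, tn = 9))
  cm2 <- rbind(c(2, 1), c(0, 3))
  expect_equal(per_class_counts(cm2, 1), c(tp = 2, fp = 0, fn = 1, tn = 3))
  expect_equal(per_class_counts(cm2, 2), c(tp = 3, fp = 1, fn = 0, tn = 2))
  cmr <- random_cm(5, 300, seed = 1)
  for (k in 1:5)
    expect_equal(sum(per_class_counts(cmr, k)), sum(cmr))
})

test_that("macro metrics: perfect classifier, hand-worked table, symmetry", {
  perfect <- diag(c(7, 9, 4))
  rep <- macro_metrics(perfect)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$accuracy_standard, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$f1, 1)
  expect_equal(rep$mcc, 1)

  cm <- rbind(c(2, 1), c(0, 3))
  r <- macro_metrics(cm)
  expect_equal(r$precision, (2 / 2 + 3 / 4) / 2)      # 0.875
  expect_equal(r$recall, (2 / 3 + 3 / 3) / 2)
  expect_equal(r$accuracy, (2 / 3 + 3 / 4) / 2)       # macro Jaccard
  expect_equal(r$accuracy_standard, 5 / 6)            # trace / total
  expect_equal(r$specificity, (3 / 3 + 2 / 3) / 2)
  f1_1 <- 2 * 1 * (2 / 3) / (1 + 2 / 3)
  f1_2 <- 2 * (3 / 4) * 1 / (3 / 4 + 1)
  expect_equal(r$f1, (f1_1 + f1_2) / 2)

  # macro averages invariant to simultaneous row+column permutation
  cmr <- random_cm(4, 400, seed = 2)
  p <- c(3, 1, 4, 2)
  expect_equal(macro_metrics(cmr), macro_metrics(cmr[p, p]))

  # macro recall is 1 iff the matrix is diagonal
  expect_lt(macro_metrics(cmr)$recall, 1)
  expect_error(macro_metrics(matrix(0, 2, 2)), "all zero")
})

test_that("zero-denominator classes contribute 0 with a warning", {
  # class 2 never predicted: precision for it is 0/0
  cm <- rbind(c(5, 0), c(3, 0))
  w <- capture_warnings(r <- macro_metrics(cm))
  expect_match(w, "precision", all = FALSE)
  expect_match(w, "F1", all = FALSE)
  expect_equal(r$precision, (5 / 8 + 0) / 2)
})

test_that("multiclass MCC equals the one-hot correlation oracle", {
  # oracle: correlation between the one-hot truth and prediction indicator
  # matrices, covariances summed over the class columns (the R_K
  # correlation coefficient), rebuilt sample by sample from the matrix
  mcc_oracle <- function(cm) {
    k <- nrow(cm)
    truth <- NULL; pred <- NULL
    for (i in seq_len(k)) for (j in seq_len(k)) {
      n <- cm[i, j]
      if (n > 0) {
        ti <- matrix(0, n, k); ti[, i] <- 1
        pj <- matrix(0, n, k); pj[, j] <- 1
        truth <- rbind(truth, ti); pred <- rbind(pred, pj)
      }
    }
    num <- sum(vapply(seq_len(k), function(c)
      stats::cov(truth[, c], pred[, c]), numeric(1)))
    den <- sqrt(sum(apply(truth, 2, stats::var)) *
                  sum(apply(pred, 2, stats::var)))
    num / den
  }
  for (s in 1:10) {
    cm <- random_cm(4, 150, seed = s, strength = s / 3)
    expect_lt(abs(multiclass_mcc(cm) - mcc_oracle(cm)), 1e-10)
    expect_true(multiclass_mcc(cm) >= -1 && multiclass_mcc(cm) <= 1)
  }

  expect_equal(multiclass_mcc(diag(c(3, 5, 2))), 1)
  expect_equal(multiclass_mcc(matrix(4, 3, 3)), 0)

  # K = 2 reduces to the binary MCC formula
  for (s in 1:5) {
    cm <- random_cm(2, 80, seed = 10 + s)
    tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
    binary <- (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    expect_equal(multiclass_mcc(cm), binary, tolerance = 1e-12)
  }
})

test_that("one-vs-rest AUC matches exhaustive pair enumeration", {
  # 3 classes, 6 samples: brute-force every positive-negative pair
  scores <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3),
                  c(0.2, 0.5, 0.3), c(0.3, 0.3, 0.4), c(0.2, 0.2, 0.6))
  labels <- c(1, 1, 2, 2, 3, 3)
  auc_oracle <- function(scores, labels) {
    k <- ncol(scores)
    aucs <- numeric(k)
    for (cls in seq_len(k)) {
      pos <- which(labels == cls); neg <- which(labels != cls)
      tot <- 0
      for (i in pos) for (j in neg) {
        tot <- tot + (scores[i, cls] > scores[j, cls]) +
          0.5 * (scores[i, cls] == scores[j, cls])
      }
      aucs[cls] <- tot / (length(pos) * length(neg))
    }
    mean(aucs)
  }
  expect_equal(auc_ovr(scores, labels), auc_oracle(scores, labels))

  # random tie-free scores agree with the rank-based route
  set.seed(3)
  sc <- matrix(rnorm(40 * 3), 40, 3)
  lb <- sample(3, 40, replace = TRUE)
  expect_equal(auc_ovr(sc, lb), auc_oracle(sc, lb), tolerance = 1e-12)

  # perfect separation and uninformative scores
  perf <- rbind(c(1, 0), c(0.9, 0), c(0, 1), c(0, 0.8))
  expect_equal(auc_ovr(perf, c(1, 1, 2, 2)), 1)
  expect_equal(auc_ovr(matrix(0.5, 6, 2), c(1, 1, 1, 2, 2, 2)), 0.5)

  # strict mode scores ties as misses
  expect_equal(auc_ovr(matrix(0.5, 6, 2), c(1, 1, 1, 2, 2, 2),
                       ties = "strict"), 0)

  # class absent from the labels is skipped with a warning
  expect_warning(a <- auc_ovr(sc, pmin(lb, 2)), "skipped")
  expect_true(a >= 0 && a <= 1)
  expect_error(auc_ovr(matrix(1, 3, 1), c(1, 1, 1)), "no class")
})

test_that("evaluate_predictions assembles the full report", {
  set.seed(4)
  actual <- sample(3, 90, replace = TRUE)
  predicted <- ifelse(runif(90) < 0.8, actual, sample(3, 90, replace = TRUE))
  scores <- matrix(runif(270), 90, 3)
  scores[cbind(seq_len(90), predicted)] <- 2
  rep <- evaluate_predictions(actual, predicted, scores)
  expect_named(rep, c("accuracy", "accuracy_standard", "precision",
                      "recall", "specificity", "f1", "mcc", "auc_ovr"))
  expect_equal(rep$accuracy_standard, mean(actual == predicted))
  expect_true(rep$auc_ovr > 0.5)

  csv <- withr::local_tempfile(fileext = ".csv")
  cm <- confusion_matrix(actual, predicted)
  write_confusion_csv(cm, csv)
  expect_equal(unname(read_confusion_csv(csv)), unname(as.matrix(cm)))
})
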
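#' Assemble a contingency table from two confusion matrices
#'
#' Default (`"side_by_side"`): a `K x 2K` table whose row `i` holds model
#' A's prediction counts for actual class `i` followed by model B's — rows
#' are actual classes, columns are the two models' predictions, and every
#' element of both matrices is used. The alternative (`"correct_counts"`)
#' is a `2 x K` table of per-class correct predictions, one row per model,
#' which frames the test as homogeneity of the two models' per-class hit
#' profiles (under it, identical matrices give a statistic of exactly 0).
#'
#' @param cm_a,cm_b `K x K` confusion matrices (rows actual, columns
#'   predicted) for the two models.
#' @param layout `"side_by_side"` (default) or `"correct_counts"`.
#' @return A numeric matrix with informative dimnames.
#' @export
build_contingency <- function(cm_a, cm_b,
                              layout = c("side_by_side", "correct_counts")) {
  layout <- match.arg(layout)
  cm_a <- check_cm(cm_a); cm_b <- check_cm(cm_b)
  if (nrow(cm_a) != nrow(cm_b))
    stop("the two confusion matrices must have the same number of classes",
         call. = FALSE)
  k <- nrow(cm_a)
  if (layout == "side_by_side") {
    tab <- cbind(cm_a, cm_b)
    dimnames(tab) <- list(actual = seq_len(k),
                          predicted = c(paste0("A", seq_len(k)),
                                        paste0("B", seq_len(k))))
  } else {
    tab <- rbind(A = diag(cm_a), B = diag(cm_b))
    colnames(tab) <- paste0("class", seq_len(k))
  }
  tab
}

#' Chi-square test of independence on a contingency table
#'
#' Expected counts `E_ij = row_i * col_j / total`; statistic
#' `sum((O - E)^2 / E)`; degrees of freedom `(R - 1)(C - 1)` after all-zero
#' rows/columns are pruned (with a warning); p-value from the upper tail of
#' the chi-square distribution. No continuity correction. A table that is
#' degenerate after pruning (a single row or column) has statistic 0, zero
#' degrees of freedom and p = 1.
#'
#' @param observed nonnegative matrix of observed frequencies.
#' @param alpha significance level (default 0.05).
#' @return An object of class `chi_square_result` with fields `statistic`,
#'   `df`, `p_value`, `significant`, `observed`, `expected`, `alpha`.
#' @export
chi_square_test <- function(observed, alpha = 0.05) {
  o <- as.matrix(observed)
  if (any(o < 0)) stop("observed frequencies must be >= 0", call. = FALSE)
  keep_r <- rowSums(o) > 0
  keep_c <- colSums(o) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero rows/columns before testing", call. = FALSE)
    o <- o[keep_r, keep_c, drop = FALSE]
  }
  total <- sum(o)
  if (total == 0) stop("contingency table has zero grand total",
                       call. = FALSE)
  r <- nrow(o); cc <- ncol(o)
  if (r < 2L || cc < 2L) {
    res <- list(statistic = 0, df = 0L, p_value = 1,
                significant = FALSE, observed = o, expected = o,
                alpha = alpha)
    class(res) <- "chi_square_result"
    return(res)
  }
  e <- outer(rowSums(o), colSums(o)) / total
  if (any(e == 0)) stop("expected frequency of 0 after pruning",
                        call. = FALSE)
  stat <- sum((o - e)^2 / e)
  df <- (r - 1L) * (cc - 1L)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  res <- list(statistic = stat, df = df, p_value = p,
              significant = p < alpha, observed = o, expected = e,
              alpha = alpha)
  class(res) <- "chi_square_result"
  res
}

#' Compare two classifiers' confusion matrices
#'
#' Builds the contingency table, runs the chi-square test, and attaches a
#' verdict: the model with the higher standard accuracy (`trace/total`) is
#' "superior"; the chi-square p-value against `alpha` says whether the
#' association carried by the table is statistically significant. The four
#' verdict phrasings mirror a superiority-with-significance summary grid.
#'
#' @param cm_a,cm_b `K x K` confusion matrices for models A and B.
#' @param alpha significance level (default 0.05).
#' @param layout contingency layout, see [build_contingency()].
#' @param model_names length-2 character vector naming the models.
#' @return An object of class `model_comparison` (extends
#'   `chi_square_result`) with fields `better_model` (`"A"`, `"B"` or
#'   `"tie"`), `acc_a`, `acc_b`, `verdict`.
#' @export
compare_models <- function(cm_a, cm_b, alpha = 0.05,
                           layout = c("side_by_side", "correct_counts"),
                           model_names = c("A", "B")) {
  layout <- match.arg(layout)
  tab <- build_contingency(cm_a, cm_b, layout)
  res <- chi_square_test(tab, alpha)
  acc_a <- sum(diag(as.matrix(cm_a))) / sum(cm_a)
  acc_b <- sum(diag(as.matrix(cm_b))) / sum(cm_b)
  better <- if (acc_a > acc_b) "A" else if (acc_b > acc_a) "B" else "tie"
  better_name <- switch(better, A = model_names[1], B = model_names[2],
                        tie = "neither")
  verdict <- if (better == "tie") {
    sprintf("models tie on accuracy (%.3f); difference %s (p = %.3g)",
            acc_a,
            if (res$significant) "significant" else "not significant",
            res$p_value)
  } else {
    sprintf("%s superior (accuracy %.3f vs %.3f); %s (p = %.3g)",
            better_name, max(acc_a, acc_b), min(acc_a, acc_b),
            if (res$significant) "statistically significant"
            else "not statistically significant",
            res$p_value)
  }
  res$better_model <- better
  res$model_names <- model_names
  res$acc_a <- acc_a
  res$acc_b <- acc_b
  res$layout <- layout
  res$verdict <- verdict
  class(res) <- c("model_comparison", "chi_square_result")
  res
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Chi-square test: X-squared = %.4f, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$verdict)) cat(" ", x$verdict, "\n")
  invisible(x)
}

#' Tidy a chi-square result into per-cell terms
#'
#' @param x a `chi_square_result`.
#' @param ... unused.
#' @return A tibble with one row per cell: observed, expected, and the
#'   cell's contribution to the statistic.
#' @export
tidy.chi_square_result <- function(x, ...) {
  o <- x$observed; e <- x$expected
  rn <- rownames(o); if (is.null(rn)) rn <- as.character(seq_len(nrow(o)))
  cn <- colnames(o); if (is.null(cn)) cn <- as.character(seq_len(ncol(o)))
  tibble::tibble(
    row = rep(rn, times = ncol(o)),
    col = rep(cn, each = nrow(o)),
    observed = as.vector(o),
    expected = as.vector(e),
    contribution = if (x$df > 0) as.vector((o - e)^2 / e) else 0
  )
}

#' One-row summary of a chi-square comparison
#'
#' @param x a `chi_square_result` or `model_comparison`.
#' @param ... unused.
#' @return A one-row tibble: statistic, df, p-value, significance, and —
#'   for model comparisons — both accuracies and the better model.
#' @export
glance.chi_square_result <- function(x, ...) {
  out <- tibble::tibble(statistic = x$statistic, df = x$df,
                        p_value = x$p_value, alpha = x$alpha,
                        significant = x$significant)
  if (!is.null(x$better_model)) {
    out$acc_a <- x$acc_a
    out$acc_b <- x$acc_b
    out$better_model <- x$better_model
  }
  out
}

#' Plot observed vs expected cell contributions
#'
#' @param object a `chi_square_result`.
#' @param ... unused.
#' @return A ggplot tile map of per-cell contributions to the statistic.
#' @export
autoplot.chi_square_result <- function(object, ...) {
  df <- tidy.chi_square_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$contribution)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "column", y = "row", fill = "(O-E)^2/E",
                  title = sprintf("Chi-square contributions (p = %.3g)",
                                  object$p_value))
}
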
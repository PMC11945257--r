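test_that("contingency assembly preserves both matrices", {
  a <- random_cm(7, 490, seed = 1)
  b <- random_cm(7, 490, seed = 2)
  tab <- build_contingency(a, b)
  expect_equal(dim(tab), c(7L, 14L))
  expect_equal(unname(colSums(tab)[1:7]), unname(colSums(a)))
  expect_equal(unname(colSums(tab)[8:14]), unname(colSums(b)))

  a2 <- rbind(c(3, 1), c(0, 4)); b2 <- rbind(c(2, 2), c(1, 3))
  expect_equal(unname(build_contingency(a2, b2)),
               rbind(c(3, 1, 2, 2), c(0, 4, 1, 3)))

  cc <- build_contingency(a2, b2, layout = "correct_counts")
  expect_equal(unname(cc), rbind(c(3, 4), c(2, 3)))

  expect_error(build_contingency(a, random_cm(5, 100, seed = 3)),
               "same number of classes")
})

test_that("chi-square statistic matches hand evaluation and closed form", {
  tab <- rbind(c(10, 20), c(30, 40))
  res <- chi_square_test(tab)
  # termwise oracle: E = outer(rowsums, colsums)/N evaluated by hand
  e <- rbind(c(12, 18), c(28, 42))
  hand <- sum((tab - e)^2 / e)
  expect_equal(res$statistic, hand)
  expect_equal(res$statistic, 50 / 63)
  # 2x2 closed form N(ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(res$statistic,
               100 * (10 * 40 - 20 * 30)^2 / (30 * 70 * 40 * 60))
  expect_equal(res$df, 1L)
  expect_equal(res$p_value,
               stats::pchisq(50 / 63, 1, lower.tail = FALSE))

  # df of a 7 x 14 model-comparison table
  t7 <- build_contingency(random_cm(7, 700, seed = 4),
                          random_cm(7, 700, seed = 5))
  expect_equal(chi_square_test(t7)$df, 78L)
})

test_that("chi-square agrees with the stats::chisq.test oracle", {
  for (s in 1:8) {
    set.seed(s)
    tab <- matrix(rpois(12, 20) + 1, 3, 4)
    ours <- chi_square_test(tab)
    ref <- stats::chisq.test(tab, correct = FALSE)
    expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-8)
    expect_lt(abs(ours$p_value - ref$p.value), 1e-8)
    expect_equal(ours$df, unname(ref$parameter))
  }
})

test_that("degenerate and malformed tables are handled", {
  # independence-structured table: O == E exactly, statistic 0
  tab <- outer(c(10, 20), c(3, 7)) / 10
  res <- chi_square_test(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # all-zero row pruned with a warning; single remaining row -> p = 1
  expect_warning(one <- chi_square_test(rbind(c(5, 5), c(0, 0))),
                 "all-zero")
  expect_equal(one$statistic, 0)
  expect_equal(one$df, 0L)
  expect_equal(one$p_value, 1)

  expect_error(suppressWarnings(chi_square_test(matrix(0, 2, 2))),
               "zero grand total")
  expect_error(chi_square_test(rbind(c(-1, 2), c(3, 4))), ">= 0")

  # statistic invariant to simultaneous class permutation in both matrices
  a <- random_cm(4, 200, seed = 6); b <- random_cm(4, 200, seed = 7)
  p <- c(2, 4, 1, 3)
  s1 <- chi_square_test(build_contingency(a, b))$statistic
  s2 <- chi_square_test(build_contingency(a[p, p], b[p, p]))$statistic
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("model comparison verdicts follow accuracy and significance", {
  # strongly different models: perfect diagonal vs uniform guessing
  k <- 7; n_per <- 70
  perfect <- diag(rep(n_per, k))
  uniform <- matrix(n_per / k, k, k)
  res <- compare_models(perfect, uniform)
  expect_s3_class(res, "model_comparison")
  expect_equal(res$better_model, "A")
  expect_true(res$significant)
  expect_lt(res$p_value, 0.05)

  # swapping the models flips the verdict but not the p-value
  swapped <- compare_models(uniform, perfect)
  expect_equal(swapped$better_model, "B")
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)

  # identical matrices tie; under the correct-counts homogeneity layout
  # the statistic is exactly 0 and nothing is significant
  a <- random_cm(4, 300, seed = 8)
  same <- compare_models(a, a, layout = "correct_counts")
  expect_equal(same$better_model, "tie")
  expect_equal(same$statistic, 0)
  expect_false(same$significant)
  # identical uninformative matrices are not significant under either layout
  flat <- matrix(10, 4, 4)
  expect_false(compare_models(flat, flat)$significant)

  expect_match(res$verdict, "superior")
  expect_match(same$verdict, "tie")
})

test_that("tidy and glance summarize a comparison", {
  a <- random_cm(3, 150, seed = 9); b <- random_cm(3, 150, seed = 10)
  res <- compare_models(a, b)
  td <- tidy(res)
  expect_named(td, c("row", "col", "observed", "expected", "contribution"))
  expect_equal(sum(td$contribution), res$statistic, tolerance = 1e-12)
  gl <- glance(res)
  expect_equal(gl$statistic, res$statistic)
  expect_equal(gl$better_model, res$better_model)
  expect_true(all(c("acc_a", "acc_b") %in% names(gl)))
})
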
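test_that("feature-map shapes follow the four-halvings law", {
  m <- build_cnn(cnn_config(input_size = 32, n_classes = 7), seed = 1)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  b4 <- extract_block4_features(m, x, flatten = FALSE)
  expect_equal(dim(b4), c(2L, 2L, 256L, 1L))
  flat <- extract_block4_features(m, x)
  expect_equal(dim(flat), c(1L, 2L * 2L * 256L))

  logits <- mycosom:::cnn_forward(m, array(x, c(32, 32, 3, 1)))$logits
  expect_equal(dim(logits), c(1L, 7L))

  m48 <- build_cnn(cnn_config(input_size = 48, n_classes = 3), seed = 1)
  b4 <- extract_block4_features(m48, array(runif(48 * 48 * 3), c(48, 48, 3)),
                                flatten = FALSE)
  expect_equal(dim(b4)[1:3], c(3L, 3L, 256L))

  expect_error(cnn_config(input_size = 100), "divisible by 16")
  expect_error(extract_block4_features(m, array(0, c(48, 48, 3))),
               "expects 32x32")
})

test_that("feature extraction is deterministic in inference mode", {
  m <- build_cnn(cnn_config(input_size = 16, n_classes = 3), seed = 2)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(extract_block4_features(m, x),
                   extract_block4_features(m, x))
})

test_that("pooled features equal independently computed channel means", {
  m <- build_cnn(cnn_config(input_size = 32, n_classes = 5), seed = 3)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  gap <- extract_gap_features(m, x)
  b4 <- extract_block4_features(m, x, flatten = FALSE)
  oracle <- t(apply(b4, 4, function(map) apply(map, 3, mean)))
  expect_equal(gap, oracle, tolerance = 1e-6)
  expect_equal(dim(gap), c(2L, 256L))

  # GAP of a constant channel is that constant
  cst <- array(0.37, c(2, 2, 256, 1))
  expect_equal(unique(as.vector(mycosom:::gap_forward(cst))), 0.37)
})

test_that("augmentation: identity policy, [0,1] closure, determinism", {
  img <- tiny_set(2, 2, 16, seed = 5)$images[, , , 1]
  id_policy <- augmentation_policy(rotation_range_deg = c(0, 0),
                                   horizontal_flip_prob = 0,
                                   jitter_brightness = 0, jitter_contrast = 0,
                                   jitter_saturation = 0, jitter_hue = 0)
  expect_identical(augment(img, id_policy), img)

  pol <- augmentation_policy()
  set.seed(11); a1 <- augment(img, pol)
  set.seed(11); a2 <- augment(img, pol)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0 & a1 <= 1))
  for (i in 1:5) {
    out <- augment(img, pol)
    expect_true(all(out >= 0 & out <= 1))
  }

  # a flip-only policy is an exact mirror
  flip_only <- augmentation_policy(rotation_range_deg = c(0, 0),
                                   horizontal_flip_prob = 1,
                                   jitter_brightness = 0, jitter_contrast = 0,
                                   jitter_saturation = 0, jitter_hue = 0)
  expect_identical(augment(img, flip_only), img[, 16:1, , drop = FALSE])

  expect_error(augmentation_policy(rotation_range_deg = c(-10, 15)),
               "symmetric")
  expect_error(augmentation_policy(jitter_hue = -0.1), ">= 0")
})

test_that("step learning-rate schedule decays by gamma every step epochs", {
  lr0 <- 1e-3
  expect_equal(lr_at(0, lr0), lr0)
  expect_equal(lr_at(6, lr0), lr0)
  expect_equal(lr_at(7, lr0), lr0 * 0.1)
  expect_equal(lr_at(14, lr0), lr0 * 0.01)
  e <- 0:20
  expect_equal(lr_at(e, lr0), lr0 * 0.1^(e %/% 7))

  # and the training loop follows it: epoch 8 lr = 0.1 x epoch 1 lr
  data <- split_stratified(tiny_set(2, 6, 16, seed = 6), 0.7, seed = 1)
  m <- build_cnn(cnn_config(input_size = 16, n_classes = 2), seed = 1)
  m <- train_cnn(m, data, train_config(batch_size = 4, max_epochs = 8,
                                       early_stop_patience = 99, seed = 1))
  expect_equal(nrow(m$history), 8L)
  expect_equal(m$history$lr[8], 0.1 * m$history$lr[1])
})

test_that("training learns separable synthetic data, rejects degenerate input", {
  data <- split_stratified(tiny_set(3, 15, 16, separability = 1, seed = 8),
                           0.7, seed = 2)
  m <- build_cnn(cnn_config(input_size = 16, n_classes = 3), seed = 2)
  m <- train_cnn(m, data, train_config(batch_size = 16, max_epochs = 8,
                                       learning_rate = 1e-3, seed = 2))
  hist <- m$history
  expect_gt(hist$train_acc[nrow(hist)], 0.9)
  expect_true(all(is.finite(hist$train_loss)))

  single <- data[data$labels == 1]
  expect_error(train_cnn(build_cnn(cnn_config(16, n_classes = 2)), single,
                         train_config(max_epochs = 1)),
               "at least 2 classes")
})

test_that("random search samples the stated grids and is seeded", {
  obj <- function(cfg) -log10(cfg$learning_rate) + cfg$batch_size / 100
  one <- random_search(n_trials = 1, seed = 3, objective = obj)
  expect_s3_class(one$best_config, "train_config")
  expect_true(one$best_config$batch_size %in% c(16L, 32L, 64L))
  expect_true(one$best_config$learning_rate %in% c(1e-2, 1e-3, 1e-4))
  expect_true(one$best_config$weight_decay %in% c(1e-3, 1e-4, 1e-5))

  a <- random_search(n_trials = 5, seed = 4, objective = obj)
  b <- random_search(n_trials = 5, seed = 4, objective = obj)
  expect_identical(a$trials, b$trials)

  # 27 trials without replacement enumerate the full 3x3x3 grid
  full <- random_search(n_trials = 27, seed = 5, objective = obj)
  combos <- unique(full$trials[, c("batch_size", "learning_rate",
                                   "weight_decay")])
  expect_equal(nrow(combos), 27L)
  # the best config under this objective is known by enumeration
  expect_equal(full$best_config$learning_rate, 1e-4)
  expect_equal(full$best_config$batch_size, 64L)

  expect_error(random_search(n_trials = 28, seed = 1, objective = obj),
               "exceeds grid size")
  expect_error(random_search(space = list(batch_size = integer(0)),
                             n_trials = 1, seed = 1, objective = obj),
               "empty")
})
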
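test_that("BMU search matches brute force with row-major tie breaking", {
  set.seed(21)
  som <- init_som(5, 4, 6, seed = 21)
  # brute-force oracle: loop all neurons, track the minimum, first wins
  bmu_oracle <- function(som, x) {
    best <- Inf; best_ij <- c(NA, NA)
    for (i in seq_len(som$rows)) for (j in seq_len(som$cols)) {
      w <- som$weights[(i - 1) * som$cols + j, ]
      d <- sqrt(sum((x - w)^2))
      if (d < best) { best <- d; best_ij <- c(i, j) }
    }
    best_ij
  }
  for (p in 1:100) {
    x <- runif(6)
    expect_identical(as.integer(find_bmu(som, x)),
                     as.integer(bmu_oracle(som, x)))
  }

  # input equal to a neuron's weights returns that neuron
  expect_identical(as.integer(find_bmu(som, som$weights[7, ])),
                   as.integer(som$coords[7, ]))

  # all-equidistant grid resolves to (1, 1)
  tie <- init_som(3, 3, 2, seed = 1)
  tie$weights <- matrix(0.5, 9, 2)
  expect_identical(as.integer(find_bmu(tie, c(0.1, 0.9))), c(1L, 1L))

  expect_error(find_bmu(som, runif(5)), "expects 6")
  expect_error(init_som(0, 3, 2), "positive")
})

test_that("radius decay and Gaussian neighborhood match closed forms", {
  expect_equal(radius_at(0, 1.5, 100), 1.5)
  expect_equal(radius_at(100, 1.5, 100), 1.5 / exp(1))
  t <- seq(0, 500, by = 50)
  expect_true(all(diff(radius_at(t, 2, 200)) < 0))

  expect_equal(neighborhood(c(3, 3), c(3, 3), 0.7), 1)
  expect_equal(neighborhood(c(2, 2), c(2, 3), 1), exp(-0.5))
  # independently evaluated Gaussian at grid distance sqrt(5)
  expect_equal(neighborhood(c(1, 1), c(2, 3), 1.3),
               exp(-5 / (2 * 1.3^2)))
  h <- vapply(1:5, function(d) neighborhood(c(1, 1), c(1, 1 + d), 1.2),
              numeric(1))
  expect_true(all(diff(h) < 0))
})

test_that("weight update follows the competitive learning rule", {
  som <- init_som(3, 3, 4, seed = 2)
  x <- runif(4)
  # alpha = 1 at the BMU (h = 1) jumps exactly onto x
  bmu <- find_bmu(som, x)
  upd <- update_weights(som, x, bmu, alpha_t = 1, sigma_t = 1e-6)
  idx <- (bmu[1] - 1) * som$cols + bmu[2]
  expect_equal(upd$weights[idx, ], x)

  # alpha = 0 changes nothing
  upd0 <- update_weights(som, x, bmu, alpha_t = 0, sigma_t = 1)
  expect_identical(upd0$weights, som$weights)

  # elementwise loop oracle of the update equation on the full 3x3 grid
  alpha <- 0.3; sigma <- 0.8
  upd2 <- update_weights(som, x, bmu, alpha, sigma)
  for (i in 1:3) for (j in 1:3) {
    n_idx <- (i - 1) * 3 + j
    h <- exp(-((i - bmu[1])^2 + (j - bmu[2])^2) / (2 * sigma^2))
    expected <- som$weights[n_idx, ] +
      alpha * h * (x - som$weights[n_idx, ])
    expect_equal(upd2$weights[n_idx, ], expected, tolerance = 1e-12)
  }
})

test_that("training converges to a repeated point and is deterministic", {
  som <- init_som(2, 2, 3, seed = 3, sigma0 = 1, alpha0 = 0.5, n_iter = 500)
  x <- matrix(rep(c(0.2, 0.7, 0.4), each = 1), 1, 3)
  trained <- fit_som(som, x[rep(1, 5), ])
  bmu <- find_bmu(trained, x[1, ])
  idx <- (bmu[1] - 1) * 2 + bmu[2]
  expect_lt(sqrt(sum((trained$weights[idx, ] - x[1, ])^2)), 1e-3)

  t2 <- fit_som(som, x[rep(1, 5), ])
  expect_identical(trained$weights, t2$weights)

  expect_error(fit_som(som, matrix(numeric(0), 0, 3)), "empty")
})

test_that("quantization error decreases on clustered data", {
  set.seed(4)
  x <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
             matrix(rnorm(100, 3, 0.1), 50, 2))
  som <- init_som(4, 4, 2, seed = 4, sigma0 = 1.5, n_iter = 800)
  qe0 <- quantization_error(som, x)
  trained <- fit_som(som, x)
  qe1 <- quantization_error(trained, x)
  expect_lte(qe1, qe0)
  # checkpoints recorded at init + every 10%
  expect_equal(nrow(trained$quantization), 11L)
  expect_equal(trained$quantization$qe[1], qe0)
  expect_equal(trained$quantization$qe[11], qe1)
})

test_that("neuron labeling: majority, ties, propagation, totality", {
  som <- init_som(2, 2, 2, seed = 5)
  som$weights <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  # three samples at neuron 1 with classes 2,2,3 and two at neuron 4 with 1,2
  x <- rbind(c(0, 0), c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  y <- c(2, 2, 3, 1, 2)
  lab <- label_neurons(som, x, y)
  expect_equal(lab$labels[1], 2L)   # majority
  expect_equal(lab$labels[4], 1L)   # tie -> smallest class
  # empty neurons 2 and 3 inherit from their nearest labeled neighbors
  expect_false(any(is.na(lab$labels)))
  expect_true(all(lab$labels %in% c(1L, 2L)))

  # single-class data propagates that class everywhere
  uni <- label_neurons(som, x, rep(3, 5))
  expect_true(all(uni$labels == 3L))

  expect_error(label_neurons(som, x, NULL), "labels")
  expect_error(predict(som, c(0, 0)), "unlabeled")
})

test_that("BMU-label prediction separates Gaussian clusters", {
  set.seed(6)
  centers <- rbind(rep(0, 4), rep(2, 4))
  make <- function(n) {
    y <- rep(1:2, each = n / 2)
    x <- centers[y, ] + matrix(rnorm(n * 4, 0, 0.3), n, 4)
    list(x = x, y = y)
  }
  tr <- make(100); te <- make(50)
  som <- som_fit(tr$x, tr$y, rows = 5, cols = 5, sigma0 = 1, alpha0 = 0.5,
                 n_iter = 1000, seed = 6)
  acc <- mean(predict(som, te$x) == te$y)
  expect_gt(acc, 0.95)

  # prediction of a probe equal to a labeled neuron's weights is its label
  expect_equal(predict(som, som$weights[13, ]), som$labels[13])
})

test_that("class scores are consistent with BMU prediction", {
  set.seed(7)
  x <- matrix(runif(60 * 3), 60, 3)
  y <- sample(3, 60, replace = TRUE)
  som <- som_fit(x, y, rows = 4, cols = 4, n_iter = 400, seed = 7)
  probes <- matrix(runif(100 * 3), 100, 3)
  sc <- class_scores(som, probes)
  expect_equal(max.col(sc, ties.method = "first"),
               as.integer(predict(som, probes)))

  # probe sitting exactly on a class-k neuron: score_k = 0, others <= 0
  k <- som$labels[5]
  s1 <- class_scores(som, som$weights[5, ])
  expect_equal(s1[k], 0)
  expect_true(all(s1 <= 0))

  # a class with no neurons scores -Inf
  som2 <- som
  som2$labels[som2$labels == 2L] <- 1L
  expect_true(all(class_scores(som2, probes)[, 2] == -Inf))
})

test_that("a 1-D manifold maps to mostly adjacent neurons on a line grid", {
  set.seed(8)
  t_ord <- seq(0, 1, length.out = 200)
  x <- cbind(t_ord, 0.5 * t_ord, t_ord^2) +
    matrix(rnorm(600, 0, 0.01), 200, 3)
  som <- init_som(1, 10, 3, seed = 8, sigma0 = 2, alpha0 = 0.5,
                  n_iter = 3000)
  som <- fit_som(som, x)
  cols <- vapply(seq_len(200), function(i) find_bmu(som, x[i, ])[2],
                 numeric(1))
  adj <- mean(abs(diff(cols)) <= 1)
  expect_gte(adj, 0.8)
})

test_that("SOM accessors: tidy/glance/label CSV and checkpoint round-trip", {
  set.seed(9)
  x <- matrix(runif(40 * 2), 40, 2)
  y <- rep(1:2, 20)
  som <- som_fit(x, y, rows = 3, cols = 3, n_iter = 200, seed = 9)
  td <- tidy(som)
  expect_equal(nrow(td), 9L)
  expect_named(td, c("row", "col", "label"))
  gl <- glance(som)
  expect_equal(gl$rows, 3L)
  expect_true(gl$labeled)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_som_labels(som, csv)
  expect_equal(nrow(utils::read.csv(csv)), 9L)

  ck <- withr::local_tempfile(fileext = ".rds")
  write_som(som, ck)
  back <- read_som(ck)
  expect_identical(back$weights, som$weights)
  expect_identical(back$labels, som$labels)
})
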
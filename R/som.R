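#' Initialize a self-organizing map grid
#'
#' Creates a rectangular Kohonen grid of `rows x cols` neurons, each with a
#' `d`-dimensional weight vector drawn i.i.d. uniform on `[0, 1]` from a
#' seeded RNG. Neurons are stored in row-major order (grid position `(i, j)`
#' is entry `(i - 1) * cols + j`), which also fixes all tie-breaking.
#'
#' @param rows,cols grid dimensions (the reference configuration is 20 x 20
#'   for CNN features, 10 x 10 for transformer-backbone features).
#' @param d input dimensionality.
#' @param seed integer RNG seed.
#' @param sigma0 initial neighborhood radius (default 1.0).
#' @param alpha0 initial learning rate (default 0.5).
#' @param n_iter default number of training iterations (default 5000).
#' @param tau decay time constant; defaults to `n_iter`.
#' @param decay learning-rate decay form, `"exponential"`
#'   (`alpha0 * exp(-t/tau)`, the default) or `"inverse_time"`
#'   (`alpha0 / (1 + 2 t / tau)`). The neighborhood radius always decays
#'   exponentially, `sigma(t) = sigma0 * exp(-t/tau)`.
#' @return An object of class `som_grid` with unassigned neuron labels.
#' @export
init_som <- function(rows, cols, d, seed = 1, sigma0 = 1.0, alpha0 = 0.5,
                     n_iter = 5000, tau = n_iter,
                     decay = c("exponential", "inverse_time")) {
  decay <- match.arg(decay)
  rows <- as.integer(rows); cols <- as.integer(cols); d <- as.integer(d)
  if (rows < 1L || cols < 1L || d < 1L)
    stop("rows, cols and d must be positive", call. = FALSE)
  n <- rows * cols
  w <- with_local_seed(seed, matrix(stats::runif(n * d), n, d))
  coords <- cbind(rep(seq_len(rows), each = cols),
                  rep(seq_len(cols), times = rows))
  structure(
    list(rows = rows, cols = cols, d = d, weights = w, coords = coords,
         labels = rep(NA_integer_, n), n_classes = NA_integer_,
         sigma0 = sigma0, alpha0 = alpha0, n_iter = as.integer(n_iter),
         tau = tau, decay = decay, seed = as.integer(seed),
         quantization = NULL),
    class = "som_grid"
  )
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %d x %d neurons, d = %d%s\n", x$rows, x$cols, x$d,
              if (all(is.na(x$labels))) " (unlabeled)" else " (labeled)"))
  cat(sprintf("  sigma0 %.3g, alpha0 %.3g, n_iter %d, %s decay\n",
              x$sigma0, x$alpha0, x$n_iter, x$decay))
  invisible(x)
}

#' Best matching unit
#'
#' The neuron whose weight vector minimizes the Euclidean distance to `x`;
#' ties resolve to the smallest `(i, j)` in row-major order.
#'
#' @param som a `som_grid`.
#' @param x numeric vector of length `som$d`.
#' @return Integer vector `c(i, j)` (1-based grid coordinates).
#' @export
find_bmu <- function(som, x) {
  idx <- bmu_index(som, x)
  som$coords[idx, ]
}

bmu_index <- function(som, x) {
  if (length(x) != som$d)
    stop(sprintf("input has length %d, SOM expects %d", length(x), som$d),
         call. = FALSE)
  diff <- som$weights - matrix(x, nrow(som$weights), som$d, byrow = TRUE)
  which.min(rowSums(diff * diff))   # first minimum = row-major tie rule
}

# BMU indices for every row of X at once (used by labeling/prediction)
bmu_index_batch <- function(som, x_mat) {
  if (ncol(x_mat) != som$d)
    stop(sprintf("inputs have %d columns, SOM expects %d", ncol(x_mat),
                 som$d), call. = FALSE)
  w2 <- rowSums(som$weights^2)
  d2 <- matrix(w2, nrow(x_mat), length(w2), byrow = TRUE) -
    2 * tcrossprod(x_mat, som$weights)
  max.col(-d2, ties.method = "first")
}

#' Neighborhood radius schedule
#'
#' `sigma(t) = sigma0 * exp(-t / tau)`.
#'
#' @param t training iteration (0-based).
#' @param sigma0 initial radius (> 0).
#' @param tau decay time constant (> 0).
#' @return The radius at iteration `t`.
#' @export
radius_at <- function(t, sigma0, tau) {
  stopifnot(t >= 0, sigma0 > 0, tau > 0)
  sigma0 * exp(-t / tau)
}

alpha_at <- function(t, alpha0, tau, decay) {
  if (decay == "exponential") alpha0 * exp(-t / tau)
  else alpha0 / (1 + 2 * t / tau)
}

#' Gaussian neighborhood function
#'
#' `h = exp(-dist^2 / (2 sigma^2))` where `dist` is the Euclidean distance
#' between the BMU's and the neuron's grid coordinates.
#'
#' @param bmu,neuron integer grid coordinates `c(i, j)`.
#' @param sigma_t current neighborhood radius (> 0).
#' @return The neighborhood weight in `(0, 1]`.
#' @export
neighborhood <- function(bmu, neuron, sigma_t) {
  stopifnot(sigma_t > 0)
  d2 <- sum((bmu - neuron)^2)
  exp(-d2 / (2 * sigma_t^2))
}

#' One competitive weight update
#'
#' Moves every neuron toward the input by
#' `w <- w + alpha_t * h(bmu, neuron, sigma_t) * (x - w)`.
#'
#' @param som a `som_grid`.
#' @param x input vector.
#' @param bmu BMU grid coordinates `c(i, j)`.
#' @param alpha_t current learning rate in `[0, 1]` (0 leaves all weights
#'   unchanged).
#' @param sigma_t current neighborhood radius.
#' @return The updated `som_grid`.
#' @export
update_weights <- function(som, x, bmu, alpha_t, sigma_t) {
  stopifnot(alpha_t >= 0, alpha_t <= 1)
  d2 <- (som$coords[, 1] - bmu[1])^2 + (som$coords[, 2] - bmu[2])^2
  h <- exp(-d2 / (2 * sigma_t^2))
  diff <- matrix(x, nrow(som$weights), som$d, byrow = TRUE) - som$weights
  som$weights <- som$weights + (alpha_t * h) * diff
  som
}

#' Train a SOM by competitive learning
#'
#' For `t = 0 .. n_iter - 1`: draw one training vector uniformly at random
#' (with replacement, seeded), find its BMU, and update all neurons with the
#' Gaussian neighborhood at radius `sigma(t)` and learning rate `alpha(t)`.
#' The quantization error (mean distance from every training vector to its
#' BMU) is recorded at initialization and after every 10% of iterations.
#'
#' @param som an [init_som()] grid.
#' @param x `N x d` matrix of training vectors.
#' @param n_iter number of iterations; defaults to the grid's setting.
#' @param seed RNG seed for the sampling sequence; defaults to the grid's.
#' @return The trained `som_grid`; `$quantization` is a tibble of
#'   `(iteration, qe)` checkpoints.
#' @export
fit_som <- function(som, x, n_iter = som$n_iter, seed = som$seed) {
  stopifnot(inherits(som, "som_grid"))
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  if (ncol(x) != som$d)
    stop(sprintf("training vectors have %d columns, SOM expects %d",
                 ncol(x), som$d), call. = FALSE)
  n_iter <- as.integer(n_iter)
  ck_every <- max(1L, n_iter %/% 10L)
  qe_rows <- list(tibble::tibble(iteration = 0L, qe = quantization_error(som, x)))
  tau <- som$tau
  with_local_seed(seed, {
    draws <- sample.int(nrow(x), n_iter, replace = TRUE)
    for (t0 in seq_len(n_iter)) {
      t <- t0 - 1L                       # schedules are 0-based
      xi <- x[draws[t0], ]
      idx <- bmu_index(som, xi)
      sigma_t <- radius_at(t, som$sigma0, tau)
      alpha_t <- alpha_at(t, som$alpha0, tau, som$decay)
      d2 <- (som$coords[, 1] - som$coords[idx, 1])^2 +
        (som$coords[, 2] - som$coords[idx, 2])^2
      h <- exp(-d2 / (2 * sigma_t^2))
      diff <- matrix(xi, nrow(som$weights), som$d, byrow = TRUE) - som$weights
      som$weights <- som$weights + (alpha_t * h) * diff
      if (t0 %% ck_every == 0L)
        qe_rows[[length(qe_rows) + 1L]] <-
          tibble::tibble(iteration = t0, qe = quantization_error(som, x))
    }
  })
  som$quantization <- do.call(rbind, qe_rows)
  som
}

#' Quantization error
#'
#' Mean Euclidean distance from each input vector to its BMU's weights.
#'
#' @param som a `som_grid`.
#' @param x `N x d` matrix.
#' @return A nonnegative scalar.
#' @export
quantization_error <- function(som, x) {
  x <- as.matrix(x)
  idx <- bmu_index_batch(som, x)
  mean(sqrt(rowSums((x - som$weights[idx, , drop = FALSE])^2)))
}

#' Label neurons by majority vote
#'
#' Maps every training vector to its BMU and labels each neuron with the
#' majority class among the vectors it received (ties to the smallest class
#' index). Neurons that received no vectors inherit the label of the nearest
#' labeled neuron in weight space (ties to row-major order), so every neuron
#' ends up labeled.
#'
#' @param som a trained `som_grid`.
#' @param x `N x d` matrix of training vectors.
#' @param y integer class labels in `1..K` for the rows of `x`.
#' @return The labeled `som_grid`.
#' @export
label_neurons <- function(som, x, y) {
  x <- as.matrix(x)
  if (is.null(y) || length(y) != nrow(x))
    stop("labels y must be supplied, one per training vector", call. = FALSE)
  y <- as.integer(y)
  k <- max(y)
  idx <- bmu_index_batch(som, x)
  n_neurons <- nrow(som$weights)
  labels <- rep(NA_integer_, n_neurons)
  for (nn in unique(idx)) {
    counts <- tabulate(y[idx == nn], nbins = k)
    labels[nn] <- which.max(counts)     # first max = smallest class index
  }
  empty <- which(is.na(labels))
  filled <- which(!is.na(labels))
  if (length(empty) > 0L && length(filled) > 0L) {
    for (nn in empty) {
      diff <- som$weights[filled, , drop = FALSE] -
        matrix(som$weights[nn, ], length(filled), som$d, byrow = TRUE)
      labels[nn] <- labels[filled[which.min(rowSums(diff * diff))]]
    }
  }
  som$labels <- labels
  som$n_classes <- k
  som
}

#' Predict with a labeled SOM
#'
#' Assigns each input the label of its best matching unit.
#'
#' @param object a labeled `som_grid`.
#' @param newdata a vector of length `d` or an `N x d` matrix.
#' @param type `"class"` (default) or `"scores"` (see [class_scores()]).
#' @param ... unused.
#' @return Integer labels, or an `N x K` score matrix.
#' @export
predict.som_grid <- function(object, newdata, type = c("class", "scores"),
                             ...) {
  type <- match.arg(type)
  if (all(is.na(object$labels)))
    stop("SOM is unlabeled; call label_neurons() first", call. = FALSE)
  x <- if (is.null(dim(newdata))) matrix(newdata, 1L) else as.matrix(newdata)
  if (type == "scores") return(class_scores(object, x))
  idx <- bmu_index_batch(object, x)
  object$labels[idx]
}

#' Per-class SOM scores
#'
#' For class `k`, the score of input `x` is minus the distance to the
#' nearest neuron labeled `k` (higher = closer); a class with no neurons
#' scores `-Inf`. The arg-max of the scores coincides with the BMU-label
#' prediction, which makes the scores usable for one-vs-rest AUC.
#'
#' @param som a labeled `som_grid`.
#' @param x a vector of length `d` or an `N x d` matrix.
#' @return A `K`-vector or `N x K` matrix of scores.
#' @export
class_scores <- function(som, x) {
  if (all(is.na(som$labels)))
    stop("SOM is unlabeled; call label_neurons() first", call. = FALSE)
  single <- is.null(dim(x))
  xm <- if (single) matrix(x, 1L) else as.matrix(x)
  k <- som$n_classes
  w2 <- rowSums(som$weights^2)
  d2 <- matrix(w2, nrow(xm), length(w2), byrow = TRUE) -
    2 * tcrossprod(xm, som$weights) +
    matrix(rowSums(xm^2), nrow(xm), length(w2))
  d2[d2 < 0] <- 0
  scores <- matrix(-Inf, nrow(xm), k)
  for (cls in seq_len(k)) {
    cols <- which(som$labels == cls)
    if (length(cols) > 0L)
      scores[, cls] <- -sqrt(apply(d2[, cols, drop = FALSE], 1, min))
  }
  if (single) scores[1, ] else scores
}

#' Fit a supervised SOM classifier in one call
#'
#' Convenience wrapper: [init_som()] + [fit_som()] + [label_neurons()].
#'
#' @param x `N x d` matrix of feature vectors.
#' @param y integer class labels in `1..K`.
#' @param rows,cols grid dimensions (default 20 x 20).
#' @param standardize z-score the columns of `x` before training (off by
#'   default). The centering/scaling vectors are stored in the returned
#'   object's `standardize` field; apply them to new inputs before
#'   prediction.
#' @inheritParams init_som
#' @return A labeled, trained `som_grid`.
#' @export
som_fit <- function(x, y, rows = 20, cols = 20, sigma0 = 1.0, alpha0 = 0.5,
                    n_iter = 5000, tau = n_iter,
                    decay = c("exponential", "inverse_time"), seed = 1,
                    standardize = FALSE) {
  decay <- match.arg(decay)
  x <- as.matrix(x)
  if (standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    x <- scale(x, center = mu, scale = sdv)
    attr(x, "scaled:center") <- NULL; attr(x, "scaled:scale") <- NULL
  }
  som <- init_som(rows, cols, ncol(x), seed = seed, sigma0 = sigma0,
                  alpha0 = alpha0, n_iter = n_iter, tau = tau, decay = decay)
  som <- fit_som(som, x)
  som <- label_neurons(som, x, y)
  if (standardize) som$standardize <- list(center = mu, scale = sdv)
  som
}

#' Tidy a SOM grid into one row per neuron
#'
#' @param x a `som_grid`.
#' @param ... unused.
#' @return A tibble with columns `row`, `col`, `label`.
#' @export
tidy.som_grid <- function(x, ...) {
  tibble::tibble(row = x$coords[, 1], col = x$coords[, 2], label = x$labels)
}

#' One-row summary of a SOM grid
#'
#' @param x a `som_grid`.
#' @param ... unused.
#' @return A tibble with grid shape, dimensionality, iteration count and
#'   final quantization error.
#' @export
glance.som_grid <- function(x, ...) {
  tibble::tibble(
    rows = x$rows, cols = x$cols, d = x$d, n_iter = x$n_iter,
    sigma0 = x$sigma0, alpha0 = x$alpha0, decay = x$decay,
    labeled = !all(is.na(x$labels)),
    final_qe = if (is.null(x$quantization)) NA_real_
               else x$quantization$qe[nrow(x$quantization)])
}

#' Plot the label map of a SOM grid
#'
#' @param object a labeled `som_grid`.
#' @param ... unused.
#' @return A ggplot tile map of neuron labels.
#' @export
autoplot.som_grid <- function(object, ...) {
  df <- tidy.som_grid(object)
  df$label <- factor(df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "class",
                  title = "SOM neuron label map")
}

#' Write a SOM label map as CSV
#'
#' One row per neuron with columns `row`, `col`, `label`.
#'
#' @param som a labeled `som_grid`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_som_labels <- function(som, path) {
  utils::write.csv(tidy.som_grid(som), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a SOM checkpoint
#'
#' Round-trips the full grid (weights, labels, hyperparameters, seed).
#'
#' @param som a `som_grid`.
#' @param path file path.
#' @return `read_som()` returns the `som_grid`; `write_som()` returns
#'   `path` invisibly.
#' @export
write_som <- function(som, path) {
  saveRDS(som, path)
  invisible(path)
}

#' @rdname write_som
#' @export
read_som <- function(path) {
  som <- readRDS(path)
  stopifnot(inherits(som, "som_grid"))
  som
}
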
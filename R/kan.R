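#' Sine-activation Kolmogorov-Arnold classification head
#'
#' Parameters of the linear-sine-linear head placed on the CNN's pooled
#' 256-dimensional features: `y = W2 %*% sin(W1 %*% x + b1) + b2` with
#' `W1` of shape `hidden x d_in` (default 128 x 256) and `W2` of shape
#' `n_classes x hidden` (default 7 x 128). Weights are initialized uniform
#' on `[-1, 1] / sqrt(fan_in)` from a seeded RNG; biases start at zero.
#'
#' @param d_in input dimensionality (default 256).
#' @param hidden hidden width (default 128).
#' @param n_classes number of classes (default 7).
#' @param seed integer RNG seed.
#' @return An object of class `kan_params`.
#' @export
kan_params <- function(d_in = 256, hidden = 128, n_classes = 7, seed = 1) {
  d_in <- as.integer(d_in); hidden <- as.integer(hidden)
  n_classes <- as.integer(n_classes)
  stopifnot(d_in >= 1, hidden >= 1, n_classes >= 2)
  with_local_seed(seed, {
    w1 <- matrix(stats::runif(hidden * d_in, -1, 1) / sqrt(d_in),
                 hidden, d_in)
    w2 <- matrix(stats::runif(n_classes * hidden, -1, 1) / sqrt(hidden),
                 n_classes, hidden)
  })
  structure(
    list(W1 = w1, b1 = numeric(hidden), W2 = w2, b2 = numeric(n_classes),
         d_in = d_in, hidden = hidden, n_classes = n_classes),
    class = "kan_params"
  )
}

#' @export
print.kan_params <- function(x, ...) {
  cat(sprintf("<kan_params> %d -> sin(%d) -> %d\n", x$d_in, x$hidden,
              x$n_classes))
  invisible(x)
}

#' Forward pass of the sine-activation head
#'
#' `z = W1 x + b1`, `h = sin(z)` elementwise, `y = W2 h + b2`.
#'
#' @param x a vector of length `d_in` or an `N x d_in` matrix.
#' @param params a [kan_params()] object.
#' @return A `K`-vector (vector input) or `N x K` matrix of logits.
#' @export
kan_forward <- function(x, params) {
  stopifnot(inherits(params, "kan_params"))
  single <- is.null(dim(x))
  xm <- if (single) matrix(x, 1L) else as.matrix(x)
  if (ncol(xm) != params$d_in)
    stop(sprintf("input has %d columns, head expects %d", ncol(xm),
                 params$d_in), call. = FALSE)
  z <- tcrossprod(xm, params$W1) +
    matrix(params$b1, nrow(xm), params$hidden, byrow = TRUE)
  h <- sin(z)
  y <- tcrossprod(h, params$W2) +
    matrix(params$b2, nrow(xm), params$n_classes, byrow = TRUE)
  if (single) y[1, ] else y
}

# Loss and analytic gradients for one batch (used by train_kan and by the
# finite-difference gradient check in the tests).
kan_grad <- function(x, y, params, weight_decay = 0) {
  n <- nrow(x)
  z <- tcrossprod(x, params$W1) +
    matrix(params$b1, n, params$hidden, byrow = TRUE)
  h <- sin(z)
  logits <- tcrossprod(h, params$W2) +
    matrix(params$b2, n, params$n_classes, byrow = TRUE)
  ce <- softmax_ce(logits, y)
  dlog <- ce$dlogits                       # N x K
  dW2 <- crossprod(dlog, h) + weight_decay * params$W2
  db2 <- colSums(dlog)
  dh <- dlog %*% params$W2                 # N x hidden
  dz <- dh * cos(z)
  dW1 <- crossprod(dz, x) + weight_decay * params$W1
  db1 <- colSums(dz)
  list(loss = ce$loss, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Train the sine-activation head on extracted features
#'
#' Minimizes softmax cross-entropy over [kan_forward()] outputs with Adam
#' under the step learning-rate schedule, the CNN backbone staying frozen
#' (the inputs are pre-extracted feature vectors). A stratified `val_frac`
#' hold-out is monitored and the parameters from the best validation epoch
#' are returned. `max_epochs = 0` returns the initialization unchanged.
#'
#' @param features `N x d_in` matrix of pooled CNN features.
#' @param labels integer class labels in `1..K`.
#' @param cfg a [train_config()].
#' @param hidden hidden width (default 128).
#' @param verbose print one line per epoch.
#' @return A trained `kan_params` object with a `$history` tibble.
#' @export
train_kan <- function(features, labels, cfg = train_config(), hidden = 128,
                      verbose = FALSE) {
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("need at least 2 classes to train the head", call. = FALSE)
  k <- max(y)
  params <- kan_params(d_in = ncol(x), hidden = hidden, n_classes = k,
                       seed = cfg$seed)
  if (cfg$max_epochs == 0L) return(params)
  history <- NULL
  with_local_seed(cfg$seed, {
    val_idx <- integer(0)
    for (cls in unique(y)) {
      pos <- which(y == cls)
      val_idx <- c(val_idx, sample(pos, max(1L, floor(cfg$val_frac *
                                                        length(pos)))))
    }
    tr_idx <- setdiff(seq_along(y), val_idx)
    xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
    xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]
    n <- length(yt)
    theta <- params[c("W1", "b1", "W2", "b2")]
    state <- adam_init(theta)
    step <- 0L; best_val <- Inf; best <- theta; wait <- 0L
    rows <- list()
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- lr_at(epoch - 1L, cfg$learning_rate, cfg$lr_step, cfg$lr_gamma)
      perm <- sample(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ii <- perm[start:min(start + cfg$batch_size - 1L, n)]
        params[c("W1", "b1", "W2", "b2")] <- theta
        gr <- kan_grad(xt[ii, , drop = FALSE], yt[ii], params,
                       cfg$weight_decay)
        if (!is.finite(gr$loss))
          stop("non-finite training loss; lower the learning rate",
               call. = FALSE)
        step <- step + 1L
        upd <- adam_step(theta, gr$grads, state, lr, step)
        theta <- upd$params; state <- upd$state
        ep_loss <- ep_loss + gr$loss * length(ii)
      }
      params[c("W1", "b1", "W2", "b2")] <- theta
      vl_logits <- kan_forward(xv, params)
      vl <- softmax_ce(vl_logits, yv)$loss
      va <- mean(max.col(vl_logits, ties.method = "first") == yv)
      rows[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                      train_loss = ep_loss / n,
                                      val_loss = vl, val_acc = va)
      if (verbose)
        message(sprintf("epoch %02d lr %.1e train loss %.4f val loss %.4f",
                        epoch, lr, ep_loss / n, vl))
      if (vl < best_val - 1e-8) {
        best_val <- vl; best <- theta; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    params[c("W1", "b1", "W2", "b2")] <- best
    history <- do.call(rbind, rows)
  })
  params$history <- history
  params
}
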
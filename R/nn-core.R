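# Internal neural-network primitives.
#
# All image tensors use dimension order (H, W, C, N); fully connected parts
# use samples-in-rows matrices (N x d). Convolutions are 3x3, stride 1,
# zero-padding 1, realized as im2col + one BLAS matrix product.

# Patch-extraction index for a padded (Hp x Wp x C) image: returns an
# (H*W) x (k*k*C) matrix of linear indices. Patch columns are ordered with
# the kernel row offset fastest, then kernel column, then input channel --
# the same order as `dim(W) <- c(k*k*C, Cout)` on a (k, k, C, Cout) array.
im2col_index <- function(h, w, c, k = 3L) {
  hp <- h + 2L
  ii <- rep(seq_len(h), times = w)
  jj <- rep(seq_len(w), each = h)
  base <- ii + (jj - 1L) * hp
  di <- rep(0:(k - 1L), times = k * c)
  dj <- rep(rep(0:(k - 1L), each = k), times = c)
  cc <- rep(seq_len(c) - 1L, each = k * k)
  off <- di + dj * hp + cc * hp * (w + 2L)
  outer(base, off, "+")
}

pad_hw <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  xp
}

# x: (H, W, Cin, N); w: (k, k, Cin, Cout); b: length Cout
conv_forward <- function(x, w, b, idx = NULL) {
  d <- dim(x)
  h <- d[1]; wd <- d[2]; cin <- d[3]; n <- d[4]
  k <- dim(w)[1]
  cout <- dim(w)[4]
  if (is.null(idx)) idx <- im2col_index(h, wd, cin, k)
  xp <- pad_hw(x)
  xp_mat <- matrix(xp, ncol = n)
  a <- xp_mat[as.vector(idx), , drop = FALSE]       # (HW*k2C) x N
  a <- array(a, c(h * wd, ncol(idx), n))
  cols <- matrix(aperm(a, c(1, 3, 2)), h * wd * n, ncol(idx))
  wm <- matrix(w, ncol = cout)
  out <- cols %*% wm
  out <- out + matrix(b, nrow(out), cout, byrow = TRUE)
  y <- aperm(array(out, c(h, wd, n, cout)), c(1, 2, 4, 3))
  list(out = y, cols = cols, idx = idx, dims = d, k = k)
}

conv_backward <- function(dy, w, cache) {
  d <- cache$dims
  h <- d[1]; wd <- d[2]; cin <- d[3]; n <- d[4]
  k <- cache$k
  cout <- dim(w)[4]
  dy_mat <- matrix(aperm(dy, c(1, 2, 4, 3)), h * wd * n, cout)
  wm <- matrix(w, ncol = cout)
  dw <- array(crossprod(cache$cols, dy_mat), dim(w))
  db <- colSums(dy_mat)
  dcols <- tcrossprod(dy_mat, wm)                    # (HW*N) x k2C
  darr <- aperm(array(dcols, c(h * wd, n, k * k * cin)), c(1, 3, 2))
  hp <- h + 2L; wp <- wd + 2L
  dxp_mat <- matrix(0, hp * wp * cin, n)
  # scatter-add grouped by kernel offset: for a fixed (di, dj) the target
  # indices over positions x channels are all distinct
  qmat <- matrix(seq_len(k * k * cin), nrow = k * k)  # columns = channels
  for (o in seq_len(k * k)) {
    qs <- qmat[o, ]                                   # this offset, all C
    rows <- as.vector(cache$idx[, qs])
    slice <- matrix(darr[, qs, ], h * wd * cin, n)
    dxp_mat[rows, ] <- dxp_mat[rows, ] + slice
  }
  dxp <- array(dxp_mat, c(hp, wp, cin, n))
  dx <- dxp[2:(h + 1L), 2:(wd + 1L), , , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

# Spatial batch norm over (H, W, N) per channel. Population variance.
bn_forward <- function(x, gamma, beta, running, train, eps = 1e-5,
                       momentum = 0.1) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), m, d[3])
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (xm - matrix(mu, m, d[3], byrow = TRUE)) *
    matrix(ivar, m, d[3], byrow = TRUE)
  ym <- xhat * matrix(gamma, m, d[3], byrow = TRUE) +
    matrix(beta, m, d[3], byrow = TRUE)
  y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = y, xhat = xhat, ivar = ivar, dims = d, running = running)
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$dims
  m <- d[1] * d[2] * d[4]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), m, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * matrix(gamma, m, d[3], byrow = TRUE)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dxm <- (dxhat - matrix(s1 / m, m, d[3], byrow = TRUE) -
            cache$xhat * matrix(s2 / m, m, d[3], byrow = TRUE)) *
    matrix(cache$ivar, m, d[3], byrow = TRUE)
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dy, cache) dy * cache$mask

# 2x2 max pooling, stride 2; ties routed to the first window position in
# the fixed order (top-left, bottom-left, top-right, bottom-right).
maxpool_forward <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], by = 2L); re <- ro + 1L
  co <- seq(1L, d[2], by = 2L); ce <- co + 1L
  a <- x[ro, co, , , drop = FALSE]
  b <- x[re, co, , , drop = FALSE]
  cc <- x[ro, ce, , , drop = FALSE]
  dd <- x[re, ce, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  s1 <- a == m
  s2 <- b == m & !s1
  s3 <- cc == m & !s1 & !s2
  s4 <- dd == m & !s1 & !s2 & !s3
  list(out = m, sel = list(s1, s2, s3, s4), dims = d)
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dims
  ro <- seq(1L, d[1], by = 2L); re <- ro + 1L
  co <- seq(1L, d[2], by = 2L); ce <- co + 1L
  dx <- array(0, d)
  dx[ro, co, , ] <- dy * cache$sel[[1]]
  dx[re, co, , ] <- dy * cache$sel[[2]]
  dx[ro, ce, , ] <- dy * cache$sel[[3]]
  dx[re, ce, , ] <- dy * cache$sel[[4]]
  dx
}

# Global average pooling: (H, W, C, N) -> N x C
gap_forward <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3] * d[4])   # columns ordered (C fast, N)
  t(matrix(colMeans(xm), d[3], d[4]))         # N x C
}

gap_backward <- function(dy, dims) {
  # dy: N x C -> spread evenly over H x W
  h <- dims[1]; w <- dims[2]; c <- dims[3]; n <- dims[4]
  g <- t(dy) / (h * w)                                # C x N
  array(rep(as.vector(g), each = h * w), c(h, w, c, n))
}

linear_forward <- function(x, w, b) {
  out <- x %*% w + matrix(b, nrow(x), length(b), byrow = TRUE)
  list(out = out, x = x)
}

linear_backward <- function(dy, w, cache) {
  list(dx = tcrossprod(dy, w), dw = crossprod(cache$x, dy),
       db = colSums(dy))
}

dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(out = x * mask, mask = mask)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# Cross-entropy with softmax; labels in 1..K. Returns mean loss and dlogits.
softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  mx <- apply(logits, 1, max)
  z <- logits - mx
  ez <- exp(z)
  sz <- rowSums(ez)
  logp <- z - log(sz)
  loss <- -mean(logp[cbind(seq_len(n), labels)])
  p <- ez / sz
  p[cbind(seq_len(n), labels)] <- p[cbind(seq_len(n), labels)] - 1
  list(loss = loss, dlogits = p / n, probs = ez / sz)
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# Adam with optional decoupled-from-schedule L2 (classic: wd added to grad).
adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0,
                      decay_names = character()) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && nm %in% decay_names)
      g <- g + weight_decay * params[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
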
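#' Ensemble head configuration
#'
#' The two-backbone feature-concatenation classifier: features of length
#' `dim_a` (transformer backbone, 768) and `dim_b` (residual backbone,
#' 2048) are concatenated into a unified `dim_a + dim_b` vector (2816) and
#' classified through linear(2816 -> 512), ReLU, dropout 0.5, linear
#' (512 -> 7).
#'
#' @param dim_a,dim_b lengths of the two backbones' feature vectors.
#' @param hidden hidden width of the classification block (default 512).
#' @param dropout dropout rate between the two linear layers (default 0.5).
#' @param n_classes number of classes (default 7).
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(dim_a = 768, dim_b = 2048, hidden = 512,
                            dropout = 0.5, n_classes = 7) {
  structure(
    list(dim_a = as.integer(dim_a), dim_b = as.integer(dim_b),
         unified = as.integer(dim_a + dim_b), hidden = as.integer(hidden),
         dropout = dropout, n_classes = as.integer(n_classes)),
    class = "ensemble_config"
  )
}

#' Concatenate two backbones' feature vectors
#'
#' `fa` followed by `fb`; element 1 of `fb` lands at position
#' `length(fa) + 1`. Works on single vectors or on `N x d` matrices
#' (row-wise).
#'
#' @param fa,fb numeric vectors, or matrices with equal row counts.
#' @param config optional [ensemble_config()] to validate lengths against.
#' @return The unified vector (or `N x (dim_a + dim_b)` matrix).
#' @export
concat_features <- function(fa, fb, config = NULL) {
  if (is.null(dim(fa)) != is.null(dim(fb)))
    stop("fa and fb must both be vectors or both be matrices", call. = FALSE)
  la <- if (is.null(dim(fa))) length(fa) else ncol(fa)
  lb <- if (is.null(dim(fb))) length(fb) else ncol(fb)
  if (!is.null(config)) {
    if (la != config$dim_a || lb != config$dim_b)
      stop(sprintf("feature lengths (%d, %d) do not match config (%d, %d)",
                   la, lb, config$dim_a, config$dim_b), call. = FALSE)
  }
  if (is.null(dim(fa))) c(fa, fb) else {
    if (nrow(fa) != nrow(fb))
      stop("fa and fb must have the same number of rows", call. = FALSE)
    cbind(fa, fb)
  }
}

#' Build the ensemble classification block
#'
#' He-normal initialization of the fully connected block from a seeded RNG.
#'
#' @param config an [ensemble_config()].
#' @param seed integer RNG seed.
#' @return An object of class `ensemble_head`.
#' @export
build_ensemble <- function(config = ensemble_config(), seed = 1) {
  stopifnot(inherits(config, "ensemble_config"))
  with_local_seed(seed, {
    w1 <- matrix(stats::rnorm(config$unified * config$hidden,
                              sd = sqrt(2 / config$unified)),
                 config$unified, config$hidden)
    w2 <- matrix(stats::rnorm(config$hidden * config$n_classes,
                              sd = sqrt(2 / config$hidden)),
                 config$hidden, config$n_classes)
  })
  structure(
    list(config = config, W1 = w1, b1 = numeric(config$hidden),
         W2 = w2, b2 = numeric(config$n_classes), trained = FALSE),
    class = "ensemble_head"
  )
}

#' Forward pass of the ensemble classification block
#'
#' linear -> ReLU -> dropout (training mode only) -> linear. In inference
#' mode (the default) dropout is disabled and the output is deterministic.
#'
#' @param v unified feature vector of length `dim_a + dim_b`, or an
#'   `N x unified` matrix.
#' @param head an [build_ensemble()] object.
#' @param train apply dropout (draws from the current RNG state).
#' @return A `K`-vector or `N x K` matrix of logits.
#' @export
ensemble_forward <- function(v, head, train = FALSE) {
  stopifnot(inherits(head, "ensemble_head"))
  single <- is.null(dim(v))
  vm <- if (single) matrix(v, 1L) else as.matrix(v)
  if (ncol(vm) != head$config$unified)
    stop(sprintf("input has %d columns, head expects %d", ncol(vm),
                 head$config$unified), call. = FALSE)
  h <- vm %*% head$W1 + matrix(head$b1, nrow(vm), head$config$hidden,
                               byrow = TRUE)
  h <- pmax(h, 0)
  h <- dropout_forward(h, head$config$dropout, train)$out
  y <- h %*% head$W2 + matrix(head$b2, nrow(vm), head$config$n_classes,
                              byrow = TRUE)
  if (single) y[1, ] else y
}

#' Train the ensemble classification block on concatenated features
#'
#' Adam + softmax cross-entropy on [ensemble_forward()] outputs with
#' dropout active, step learning-rate schedule, stratified validation
#' hold-out and early stopping, mirroring the other heads' training loop.
#'
#' @param features `N x unified` matrix of concatenated backbone features.
#' @param labels integer class labels in `1..K`.
#' @param cfg a [train_config()].
#' @param config an [ensemble_config()] (its `unified` must match
#'   `ncol(features)`).
#' @return A trained `ensemble_head` with a `$history` tibble.
#' @export
train_ensemble <- function(features, labels, cfg = train_config(),
                           config = NULL) {
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("need at least 2 classes to train the head", call. = FALSE)
  if (is.null(config))
    config <- ensemble_config(dim_a = ncol(x), dim_b = 0,
                              n_classes = max(y))
  head <- build_ensemble(config, seed = cfg$seed)
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
    theta <- head[c("W1", "b1", "W2", "b2")]
    state <- adam_init(theta)
    step <- 0L; best_val <- Inf; best <- theta; wait <- 0L
    rows <- list()
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- lr_at(epoch - 1L, cfg$learning_rate, cfg$lr_step, cfg$lr_gamma)
      perm <- sample(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ii <- perm[start:min(start + cfg$batch_size - 1L, n)]
        xb <- xt[ii, , drop = FALSE]; yb <- yt[ii]
        # forward with caches
        f1 <- xb %*% theta$W1 + matrix(theta$b1, length(ii),
                                       config$hidden, byrow = TRUE)
        r1 <- pmax(f1, 0)
        dp <- dropout_forward(r1, config$dropout, TRUE)
        logits <- dp$out %*% theta$W2 +
          matrix(theta$b2, length(ii), config$n_classes, byrow = TRUE)
        ce <- softmax_ce(logits, yb)
        if (!is.finite(ce$loss))
          stop("non-finite training loss; lower the learning rate",
               call. = FALSE)
        dlog <- ce$dlogits
        gW2 <- crossprod(dp$out, dlog) + cfg$weight_decay * theta$W2
        gb2 <- colSums(dlog)
        ddp <- dropout_backward(tcrossprod(dlog, theta$W2), dp)
        dr1 <- ddp * (f1 > 0)
        gW1 <- crossprod(xb, dr1) + cfg$weight_decay * theta$W1
        gb1 <- colSums(dr1)
        step <- step + 1L
        upd <- adam_step(theta, list(W1 = gW1, b1 = gb1, W2 = gW2,
                                     b2 = gb2), state, lr, step)
        theta <- upd$params; state <- upd$state
        ep_loss <- ep_loss + ce$loss * length(ii)
      }
      head[c("W1", "b1", "W2", "b2")] <- theta
      vl_logits <- ensemble_forward(xv, head)
      vl <- softmax_ce(vl_logits, yv)$loss
      rows[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                      train_loss = ep_loss / n,
                                      val_loss = vl)
      if (vl < best_val - 1e-8) {
        best_val <- vl; best <- theta; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    head[c("W1", "b1", "W2", "b2")] <- best
    history <- do.call(rbind, rows)
  })
  head$trained <- TRUE
  head$history <- history
  head
}

#' Random-projection backbone stand-in
#'
#' A deterministic, seeded feature extractor used where a pretrained vision
#' backbone would normally stand: images are block-averaged to a
#' `pool x pool` grid and the flattened `pool^2 * 3` values are mapped
#' through a fixed random Gaussian projection to `out_dim` dimensions.
#' This is a synthetic stand-in — it carries no pretrained knowledge; it
#' exists so the feature-concatenation plumbing and the classification
#' block are testable with feature vectors of the published lengths
#' (768 and 2048).
#'
#' @param out_dim length of the emitted feature vectors.
#' @param seed integer RNG seed fixing the projection.
#' @param pool side length of the pooling grid (default 8).
#' @return A function mapping an [image_set] or image array to an
#'   `N x out_dim` feature matrix.
#' @export
backbone_stub <- function(out_dim, seed = 1, pool = 8) {
  out_dim <- as.integer(out_dim)
  proj_env <- new.env(parent = emptyenv())
  function(images) {
    x <- as_image_array(images)
    d <- dim(x)
    if (d[1] %% pool != 0L)
      stop("image side must be divisible by the pooling grid", call. = FALSE)
    blk <- d[1] %/% pool
    n <- d[4]
    flat <- matrix(0, n, pool * pool * 3L)
    for (i in seq_len(n)) {
      img <- x[, , , i]
      pooled <- array(0, c(pool, pool, 3L))
      for (ch in 1:3) {
        m <- img[, , ch]
        dim(m) <- c(blk, pool, blk, pool)
        pooled[, , ch] <- apply(m, c(2, 4), mean)
      }
      flat[i, ] <- as.vector(pooled)
    }
    key <- paste0("p", pool * pool * 3L)
    if (is.null(proj_env[[key]]))
      proj_env[[key]] <- with_local_seed(seed,
        matrix(stats::rnorm(pool * pool * 3L * out_dim,
                            sd = 1 / sqrt(pool * pool * 3L)),
               pool * pool * 3L, out_dim))
    tanh(flat %*% proj_env[[key]] * 3)
  }
}
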
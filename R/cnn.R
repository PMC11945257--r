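#' CNN architecture configuration
#'
#' Describes the compact four-block convolutional network used as the
#' feature extractor: four blocks of (3x3 conv, batch norm, ReLU, 2x2 max
#' pool) with 32/64/128/256 filters, global average pooling, then fully
#' connected layers 512 (with 50% dropout) -> 256 -> `n_classes`. With
#' 224-pixel inputs the fourth block emits a 14 x 14 x 256 feature map
#' (50,176 values flattened) and the pooled vector has 256 dimensions.
#'
#' @param input_size input side length in pixels; must be divisible by 16
#'   (four 2x2 poolings). Default 224.
#' @param block_filters integer vector of length 4, filters per block,
#'   strictly increasing. Default `c(32, 64, 128, 256)`.
#' @param kernel convolution kernel size (odd; default 3).
#' @param fc_sizes sizes of the two hidden fully connected layers,
#'   default `c(512, 256)`.
#' @param n_classes number of output classes (default 7).
#' @param dropout dropout rate after the first fully connected layer,
#'   in `[0, 1]` (default 0.5).
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(input_size = 224, block_filters = c(32, 64, 128, 256),
                       kernel = 3, fc_sizes = c(512, 256), n_classes = 7,
                       dropout = 0.5) {
  input_size <- as.integer(input_size)
  if (input_size %% 16L != 0L)
    stop("input_size must be divisible by 16 (four 2x2 poolings)",
         call. = FALSE)
  if (length(block_filters) != 4L || any(diff(block_filters) <= 0))
    stop("block_filters must be 4 strictly increasing values", call. = FALSE)
  if (dropout < 0 || dropout > 1) stop("dropout must lie in [0, 1]",
                                       call. = FALSE)
  structure(
    list(input_size = input_size,
         block_filters = as.integer(block_filters),
         kernel = as.integer(kernel), fc_sizes = as.integer(fc_sizes),
         n_classes = as.integer(n_classes), dropout = dropout),
    class = "cnn_config"
  )
}

#' Data augmentation policy
#'
#' Random horizontal flip, random rotation, and color jitter, with the
#' magnitudes used for training: rotation uniform in `[-15, 15]` degrees,
#' flip probability 0.5, brightness/contrast/saturation jitter 0.1 and hue
#' jitter 0.05. A policy with all magnitudes zero and flip probability zero
#' is exactly the identity.
#'
#' @param rotation_range_deg symmetric rotation range in degrees,
#'   `c(-r, r)`.
#' @param horizontal_flip_prob probability of a horizontal flip.
#' @param jitter_brightness,jitter_contrast,jitter_saturation,jitter_hue
#'   jitter magnitudes (all `>= 0`).
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(rotation_range_deg = c(-15, 15),
                                horizontal_flip_prob = 0.5,
                                jitter_brightness = 0.1,
                                jitter_contrast = 0.1,
                                jitter_saturation = 0.1,
                                jitter_hue = 0.05) {
  if (length(rotation_range_deg) == 1L)
    rotation_range_deg <- c(-abs(rotation_range_deg), abs(rotation_range_deg))
  if (abs(rotation_range_deg[1] + rotation_range_deg[2]) > 1e-12)
    stop("rotation range must be symmetric about 0", call. = FALSE)
  mags <- c(jitter_brightness, jitter_contrast, jitter_saturation, jitter_hue)
  if (any(mags < 0)) stop("jitter magnitudes must be >= 0", call. = FALSE)
  structure(
    list(rotation_range_deg = rotation_range_deg,
         horizontal_flip_prob = horizontal_flip_prob,
         jitter_brightness = jitter_brightness,
         jitter_contrast = jitter_contrast,
         jitter_saturation = jitter_saturation,
         jitter_hue = jitter_hue),
    class = "augmentation_policy"
  )
}

#' Training configuration
#'
#' Adam optimizer settings with a step learning-rate schedule (rate
#' multiplied by `lr_gamma` every `lr_step` epochs) and early stopping on a
#' held-out validation split.
#'
#' @param batch_size minibatch size (the search grid is 16/32/64).
#' @param learning_rate initial Adam learning rate (grid 1e-2/1e-3/1e-4).
#' @param weight_decay L2 penalty added to weight gradients
#'   (grid 1e-3/1e-4/1e-5).
#' @param lr_step epochs between learning-rate drops (default 7).
#' @param lr_gamma multiplicative decay factor (default 0.1).
#' @param max_epochs maximum training epochs (default 50).
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (default 5).
#' @param val_frac fraction of the training split held out for validation
#'   monitoring (default 0.1).
#' @param seed integer RNG seed for init, shuffling, dropout, augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, learning_rate = 1e-3,
                         weight_decay = 1e-4, lr_step = 7, lr_gamma = 0.1,
                         max_epochs = 50, early_stop_patience = 5,
                         val_frac = 0.1, seed = 1) {
  if (learning_rate <= 0 || weight_decay < 0)
    stop("rates must be positive", call. = FALSE)
  if (lr_gamma <= 0 || lr_gamma >= 1)
    stop("lr_gamma must lie in (0, 1)", call. = FALSE)
  structure(
    list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
         weight_decay = weight_decay, lr_step = as.integer(lr_step),
         lr_gamma = lr_gamma, max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         val_frac = val_frac, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Step learning-rate schedule
#'
#' `lr(epoch) = lr0 * gamma^floor(epoch / step)` with 0-based epochs: the
#' rate is constant for the first `step` epochs, then drops by `gamma`.
#'
#' @param epoch 0-based epoch index (first epoch is 0).
#' @param lr0 initial learning rate.
#' @param step epochs between drops.
#' @param gamma decay factor.
#' @return The learning rate at `epoch`.
#' @export
lr_at <- function(epoch, lr0, step = 7, gamma = 0.1) {
  lr0 * gamma^(epoch %/% step)
}

#' Build the four-block CNN
#'
#' Instantiates all parameters (He-normal conv/fc weights, unit batch-norm
#' scales) from a seeded RNG.
#'
#' @param config a [cnn_config()].
#' @param seed integer RNG seed for the initialization.
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(config = cnn_config(), seed = 1) {
  stopifnot(inherits(config, "cnn_config"))
  k <- config$kernel
  chans <- c(3L, config$block_filters)
  params <- list()
  running <- list()
  with_local_seed(seed, {
    for (blk in 1:4) {
      fan_in <- k * k * chans[blk]
      params[[paste0("conv", blk, "_w")]] <-
        array(stats::rnorm(k * k * chans[blk] * chans[blk + 1],
                           sd = sqrt(2 / fan_in)),
              c(k, k, chans[blk], chans[blk + 1]))
      params[[paste0("conv", blk, "_b")]] <- numeric(chans[blk + 1])
      params[[paste0("bn", blk, "_gamma")]] <- rep(1, chans[blk + 1])
      params[[paste0("bn", blk, "_beta")]] <- numeric(chans[blk + 1])
      running[[paste0("bn", blk)]] <-
        list(mean = numeric(chans[blk + 1]), var = rep(1, chans[blk + 1]))
    }
    dims <- c(config$block_filters[4], config$fc_sizes, config$n_classes)
    for (fc in 1:3) {
      params[[paste0("fc", fc, "_w")]] <-
        matrix(stats::rnorm(dims[fc] * dims[fc + 1],
                            sd = sqrt(2 / dims[fc])),
               dims[fc], dims[fc + 1])
      params[[paste0("fc", fc, "_b")]] <- numeric(dims[fc + 1])
    }
  })
  structure(
    list(config = config, params = params, running = running,
         trained = FALSE, seed = as.integer(seed)),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cnn_model> input %dx%dx3, blocks %s, fc %s -> %d%s\n",
              cfg$input_size, cfg$input_size,
              paste(cfg$block_filters, collapse = "/"),
              paste(cfg$fc_sizes, collapse = " -> "), cfg$n_classes,
              if (x$trained) " (trained)" else " (untrained)"))
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("  parameters: %s\n", format(np, big.mark = ",")))
  invisible(x)
}

# Full forward pass. x: (H, W, 3, N). Returns logits plus the block-4 map
# and pooled features; caches for backprop when keep_cache = TRUE.
cnn_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  p <- model$params
  caches <- if (keep_cache) list() else NULL
  h <- x
  for (blk in 1:4) {
    cv <- conv_forward(h, p[[paste0("conv", blk, "_w")]],
                       p[[paste0("conv", blk, "_b")]])
    bn <- bn_forward(cv$out, p[[paste0("bn", blk, "_gamma")]],
                     p[[paste0("bn", blk, "_beta")]],
                     model$running[[paste0("bn", blk)]], train)
    if (train) model$running[[paste0("bn", blk)]] <- bn$running
    rl <- relu_forward(bn$out)
    mp <- maxpool_forward(rl$out)
    if (keep_cache) {
      cv$cols <- if (blk <= 4) cv$cols else NULL
      caches[[blk]] <- list(conv = cv, bn = bn, relu = rl, pool = mp)
    }
    h <- mp$out
  }
  block4 <- h
  pooled <- gap_forward(block4)                        # N x 256
  f1 <- linear_forward(pooled, p$fc1_w, p$fc1_b)
  r1 <- relu_forward(f1$out)
  dp <- dropout_forward(r1$out, model$config$dropout, train)
  f2 <- linear_forward(dp$out, p$fc2_w, p$fc2_b)
  r2 <- relu_forward(f2$out)
  f3 <- linear_forward(r2$out, p$fc3_w, p$fc3_b)
  list(logits = f3$out, block4 = block4, pooled = pooled,
       caches = caches, head = if (keep_cache)
         list(f1 = f1, r1 = r1, dp = dp, f2 = f2, r2 = r2, f3 = f3)
       else NULL,
       model = model)
}

cnn_backward <- function(model, fwd, dlogits) {
  p <- model$params
  g <- list()
  hd <- fwd$head
  l3 <- linear_backward(dlogits, p$fc3_w, hd$f3)
  g$fc3_w <- l3$dw; g$fc3_b <- l3$db
  dr2 <- relu_backward(l3$dx, hd$r2)
  l2 <- linear_backward(dr2, p$fc2_w, hd$f2)
  g$fc2_w <- l2$dw; g$fc2_b <- l2$db
  ddp <- dropout_backward(l2$dx, hd$dp)
  dr1 <- relu_backward(ddp, hd$r1)
  l1 <- linear_backward(dr1, p$fc1_w, hd$f1)
  g$fc1_w <- l1$dw; g$fc1_b <- l1$db
  dh <- gap_backward(l1$dx, dim(fwd$block4))
  for (blk in 4:1) {
    cc <- fwd$caches[[blk]]
    dmp <- maxpool_backward(dh, cc$pool)
    drl <- relu_backward(dmp, cc$relu)
    bnb <- bn_backward(drl, p[[paste0("bn", blk, "_gamma")]], cc$bn)
    g[[paste0("bn", blk, "_gamma")]] <- bnb$dgamma
    g[[paste0("bn", blk, "_beta")]] <- bnb$dbeta
    cvb <- conv_backward(bnb$dx, p[[paste0("conv", blk, "_w")]], cc$conv)
    g[[paste0("conv", blk, "_w")]] <- cvb$dw
    g[[paste0("conv", blk, "_b")]] <- cvb$db
    dh <- cvb$dx
  }
  g
}

check_input_size <- function(model, images) {
  d <- dim(images)
  if (d[1] != model$config$input_size || d[2] != model$config$input_size)
    stop(sprintf("model expects %dx%d inputs, got %dx%d",
                 model$config$input_size, model$config$input_size,
                 d[1], d[2]), call. = FALSE)
}

as_image_array <- function(x) {
  if (inherits(x, "image_set")) return(x$images)
  if (is.array(x) && length(dim(x)) == 3L) return(array(x, c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  stop("expected an image_set or an H x W x 3 (x N) array", call. = FALSE)
}

#' Extract block-4 convolutional features
#'
#' Runs images through the four convolutional blocks (inference mode:
#' batch-norm uses running statistics, dropout disabled) and returns the
#' pre-pooling activation of the fourth block, flattened row-major over
#' (row, column, channel) — channel varies fastest, then column, then row.
#' For 224-pixel inputs each feature vector has 14 * 14 * 256 = 50,176
#' entries; these are the vectors handed to the SOM.
#'
#' @param model a [build_cnn()] model.
#' @param images an [image_set] or an `H x W x 3 (x N)` array.
#' @param flatten return an `N x (h*w*C)` matrix (default) instead of the
#'   `h x w x C x N` feature-map array.
#' @return Feature matrix or feature-map array.
#' @export
extract_block4_features <- function(model, images, flatten = TRUE) {
  x <- as_image_array(images)
  check_input_size(model, x)
  fwd <- cnn_forward(model, x, train = FALSE)
  b4 <- fwd$block4
  if (!flatten) return(b4)
  n <- dim(b4)[4]
  out <- matrix(0, n, prod(dim(b4)[1:3]))
  for (i in seq_len(n))
    out[i, ] <- as.vector(aperm(array(b4[, , , i], dim(b4)[1:3]),
                                c(3, 2, 1)))
  out
}

#' Extract global-average-pooled features
#'
#' Per-channel spatial means of the block-4 feature map: a 256-dimensional
#' vector per image (the input to the sine-activation head).
#'
#' @inheritParams extract_block4_features
#' @return An `N x 256` matrix.
#' @export
extract_gap_features <- function(model, images) {
  x <- as_image_array(images)
  check_input_size(model, x)
  cnn_forward(model, x, train = FALSE)$pooled
}

#' Predict classes with the CNN's own softmax head
#'
#' @param object a trained [build_cnn()] model.
#' @param newdata an [image_set] or image array.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... unused.
#' @return Integer labels or an `N x K` probability matrix.
#' @export
predict.cnn_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  x <- as_image_array(newdata)
  check_input_size(object, x)
  # batch to bound memory
  n <- dim(x)[4]
  k <- object$config$n_classes
  probs <- matrix(0, n, k)
  bs <- 64L
  for (start in seq(1L, n, by = bs)) {
    ii <- start:min(start + bs - 1L, n)
    logits <- cnn_forward(object, x[, , , ii, drop = FALSE])$logits
    probs[ii, ] <- softmax_probs(logits)
  }
  if (type == "prob") probs else max.col(probs, ties.method = "first")
}

#' Augment one image
#'
#' Applies, in order: horizontal flip (with the policy's probability),
#' rotation by a uniform random angle in the policy range (bilinear
#' resampling about the image center, out-of-frame pixels black), and color
#' jitter (brightness, contrast, saturation as random blend factors; hue as
#' an additive shift on the hue circle). Every step whose magnitude is zero
#' is skipped entirely, so the all-zero policy returns the input unchanged.
#' Output values are clipped to `[0, 1]`. Randomness comes from the current
#' RNG state; seed it (`set.seed`) for reproducible batches.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param policy an [augmentation_policy()].
#' @return Augmented `H x W x 3` array.
#' @export
augment <- function(image, policy = augmentation_policy()) {
  stopifnot(inherits(policy, "augmentation_policy"))
  out <- image
  if (policy$horizontal_flip_prob > 0 &&
      stats::runif(1) < policy$horizontal_flip_prob)
    out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
  r <- policy$rotation_range_deg[2]
  if (r > 0) {
    ang <- stats::runif(1, -r, r)
    out <- rotate_bilinear(out, ang)
  }
  if (policy$jitter_brightness > 0) {
    f <- stats::runif(1, 1 - policy$jitter_brightness,
                      1 + policy$jitter_brightness)
    out <- out * f
  }
  if (policy$jitter_contrast > 0) {
    f <- stats::runif(1, 1 - policy$jitter_contrast,
                      1 + policy$jitter_contrast)
    gray <- mean(0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3])
    out <- f * out + (1 - f) * gray
  }
  if (policy$jitter_saturation > 0) {
    f <- stats::runif(1, 1 - policy$jitter_saturation,
                      1 + policy$jitter_saturation)
    gray <- 0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3]
    for (ch in 1:3) out[, , ch] <- f * out[, , ch] + (1 - f) * gray
  }
  if (policy$jitter_hue > 0) {
    shift <- stats::runif(1, -policy$jitter_hue, policy$jitter_hue)
    d <- dim(out)
    rgb <- rbind(as.vector(pmin(pmax(out[, , 1], 0), 1)),
                 as.vector(pmin(pmax(out[, , 2], 0), 1)),
                 as.vector(pmin(pmax(out[, , 3], 0), 1)))
    hsv <- rgb_to_hsv_num(rgb)
    res <- hsv_to_rgb_num((hsv[1, ] + shift) %% 1, hsv[2, ], hsv[3, ])
    m <- matrix(res, ncol = 3)
    for (ch in 1:3) out[, , ch] <- matrix(m[, ch], d[1], d[2])
  }
  pmin(pmax(out, 0), 1)
}

# Bilinear rotation about the image center; angle in degrees,
# counter-clockwise; pixels sampled from outside the frame are 0.
rotate_bilinear <- function(image, angle_deg) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sy <- cos(th) * yy - sin(th) * xx + cy
  sx <- sin(th) * yy + cos(th) * xx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  out <- array(0, d)
  pick <- function(plane, yi, xi) {
    ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
    v <- numeric(length(yi))
    v[ok] <- plane[cbind(yi[ok], xi[ok])]
    v
  }
  for (ch in seq_len(d[3])) {
    plane <- image[, , ch]
    v <- (1 - fy) * (1 - fx) * pick(plane, y0, x0) +
      fy * (1 - fx) * pick(plane, y0 + 1, x0) +
      (1 - fy) * fx * pick(plane, y0, x0 + 1) +
      fy * fx * pick(plane, y0 + 1, x0 + 1)
    out[, , ch] <- matrix(v, h, w)
  }
  out
}

#' Train the CNN
#'
#' Minimizes softmax cross-entropy with Adam under a step learning-rate
#' schedule (`lr_gamma` every `lr_step` epochs, 0-based). Training images
#' are reshuffled each epoch; a stratified `val_frac` of the training split
#' is held out and its loss monitored for early stopping
#' (`early_stop_patience` epochs without improvement). The returned model
#' carries the parameters from the best validation epoch.
#'
#' @param model a [build_cnn()] model.
#' @param data an [image_set] carrying `"train"` split tags (see
#'   [split_stratified()]); only the training portion is used.
#' @param cfg a [train_config()].
#' @param policy an [augmentation_policy()] applied to each training image
#'   every epoch, or `NULL` for no augmentation.
#' @param verbose print one line per epoch.
#' @return The trained `cnn_model`; `$history` is a tibble with per-epoch
#'   learning rate, training loss/accuracy and validation loss/accuracy.
#' @export
train_cnn <- function(model, data, cfg = train_config(), policy = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "train_config"))
  train_set <- if (inherits(data, "image_set") && !all(is.na(data$split)))
    subset_split(data, "train") else data
  x <- as_image_array(train_set)
  y <- train_set$labels
  if (length(unique(y)) < 2L)
    stop("training set must contain at least 2 classes", call. = FALSE)
  check_input_size(model, x)

  history <- NULL
  with_local_seed(cfg$seed, {
    # stratified validation hold-out
    val_idx <- integer(0)
    for (cls in unique(y)) {
      pos <- which(y == cls)
      n_val <- max(1L, floor(cfg$val_frac * length(pos)))
      val_idx <- c(val_idx, sample(pos, n_val))
    }
    tr_idx <- setdiff(seq_along(y), val_idx)
    xv <- x[, , , val_idx, drop = FALSE]; yv <- y[val_idx]
    xt <- x[, , , tr_idx, drop = FALSE]; yt <- y[tr_idx]
    n <- length(yt)

    state <- adam_init(model$params)
    decay_names <- grep("_w$", names(model$params), value = TRUE)
    step <- 0L
    best_val <- Inf; best_params <- model$params
    best_running <- model$running; wait <- 0L
    rows <- list()
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- lr_at(epoch - 1L, cfg$learning_rate, cfg$lr_step, cfg$lr_gamma)
      perm <- sample(n)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ii <- perm[start:min(start + cfg$batch_size - 1L, n)]
        xb <- xt[, , , ii, drop = FALSE]
        if (!is.null(policy))
          for (j in seq_along(ii))
            xb[, , , j] <- augment(xb[, , , j], policy)
        yb <- yt[ii]
        fwd <- cnn_forward(model, xb, train = TRUE, keep_cache = TRUE)
        model <- fwd$model   # updated batch-norm running stats
        ce <- softmax_ce(fwd$logits, yb)
        if (!is.finite(ce$loss))
          stop("non-finite training loss; lower the learning rate",
               call. = FALSE)
        grads <- cnn_backward(model, fwd, ce$dlogits)
        step <- step + 1L
        upd <- adam_step(model$params, grads, state, lr, step,
                         weight_decay = cfg$weight_decay,
                         decay_names = decay_names)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + ce$loss * length(ii)
        ep_correct <- ep_correct +
          sum(max.col(fwd$logits, ties.method = "first") == yb)
      }
      # validation pass (inference mode)
      vl <- eval_loss(model, xv, yv)
      rows[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = ep_loss / n,
        train_acc = ep_correct / n, val_loss = vl$loss, val_acc = vl$acc)
      if (verbose)
        message(sprintf(
          "epoch %02d lr %.1e train loss %.4f acc %.3f val loss %.4f acc %.3f",
          epoch, lr, ep_loss / n, ep_correct / n, vl$loss, vl$acc))
      if (vl$loss < best_val - 1e-8) {
        best_val <- vl$loss
        best_params <- model$params
        best_running <- model$running
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    model$params <- best_params
    model$running <- best_running
    history <- do.call(rbind, rows)
  })
  model$trained <- TRUE
  model$history <- history
  model
}

eval_loss <- function(model, x, y) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0L
  bs <- 64L
  for (start in seq(1L, n, by = bs)) {
    ii <- start:min(start + bs - 1L, n)
    logits <- cnn_forward(model, x[, , , ii, drop = FALSE])$logits
    ce <- softmax_ce(logits, y[ii])
    loss <- loss + ce$loss * length(ii)
    correct <- correct + sum(max.col(logits, ties.method = "first") == y[ii])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Random hyperparameter search
#'
#' Samples training configurations uniformly from the three-way grid of
#' batch size, learning rate and weight decay and keeps the one with the
#' best objective value.
#'
#' @param space named list of candidate values, by default
#'   `list(batch_size = c(16, 32, 64), learning_rate = c(1e-2, 1e-3, 1e-4),
#'   weight_decay = c(1e-3, 1e-4, 1e-5))`.
#' @param n_trials number of configurations to evaluate.
#' @param seed integer RNG seed for the trial sequence.
#' @param objective function taking a [train_config()] and returning a
#'   numeric score.
#' @param maximize if `TRUE` (default) higher objective is better.
#' @param replace sample with replacement (default `FALSE`: `n_trials`
#'   equal to the grid size enumerates every combination).
#' @param base a [train_config()] supplying the non-searched fields.
#' @return List with `best_config`, `best_score`, and a tibble `trials`.
#' @export
random_search <- function(space = list(batch_size = c(16, 32, 64),
                                       learning_rate = c(1e-2, 1e-3, 1e-4),
                                       weight_decay = c(1e-3, 1e-4, 1e-5)),
                          n_trials, seed, objective, maximize = TRUE,
                          replace = FALSE, base = train_config()) {
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  if (any(lengths(space) == 0L)) stop("empty search space", call. = FALSE)
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  if (!replace && n_trials > nrow(grid))
    stop("n_trials exceeds grid size for sampling without replacement",
         call. = FALSE)
  picks <- with_local_seed(seed,
    sample.int(nrow(grid), n_trials, replace = replace))
  scores <- numeric(n_trials)
  configs <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- base
    for (nm in names(space)) cfg[[nm]] <- grid[picks[i], nm]
    cfg$batch_size <- as.integer(cfg$batch_size)
    configs[[i]] <- cfg
    scores[i] <- objective(cfg)
  }
  best <- if (maximize) which.max(scores) else which.min(scores)
  trials <- tibble::tibble(trial = seq_len(n_trials),
                           grid[picks, , drop = FALSE], score = scores)
  list(best_config = configs[[best]], best_score = scores[best],
       trials = trials)
}
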
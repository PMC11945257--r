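#' Specification for a synthetic multi-class fungal image dataset
#'
#' Describes a seeded synthetic image dataset with one visual "signature" per
#' class, used to exercise the whole classification pipeline without any
#' external image collection. Each class `k` is assigned a base hue
#' (`2*pi*k/K` on the hue circle), an oriented sinusoidal surface texture
#' (`2 + k` cycles per image), and one elliptical "cap" blob whose
#' eccentricity grows with `k`. The strength of these class-specific signals
#' scales with `separability`; Gaussian pixel noise scales with
#' `1 - separability`, so `separability = 0` gives identically distributed
#' classes and `separability = 1` gives classes distinguishable by
#' construction.
#'
#' @param n_classes number of classes `K` (default 7).
#' @param per_class_counts integer vector of length `n_classes` giving the
#'   number of images per class. The default reproduces the composition of a
#'   seven-species macrofungi collection (222, 228, 229, 243, 220, 227, 213;
#'   1582 images in total).
#' @param image_size side length in pixels (images are square; default 224).
#' @param separability real in `[0, 1]`; inter-class signal strength.
#' @param seed integer RNG seed.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_dataset()]
#' @export
synthetic_spec <- function(n_classes = 7,
                           per_class_counts = c(222L, 228L, 229L, 243L,
                                                220L, 227L, 213L),
                           image_size = 224,
                           separability = 1,
                           seed = 1) {
  n_classes <- as.integer(n_classes)
  per_class_counts <- as.integer(per_class_counts)
  image_size <- as.integer(image_size)
  if (n_classes < 1L) stop("n_classes must be positive", call. = FALSE)
  if (length(per_class_counts) != n_classes)
    stop("per_class_counts must have length n_classes", call. = FALSE)
  if (any(is.na(per_class_counts)) || any(per_class_counts < 1L))
    stop("per_class_counts must all be positive", call. = FALSE)
  if (is.na(image_size) || image_size < 1L)
    stop("image_size must be positive", call. = FALSE)
  if (!is.numeric(separability) || separability < 0 || separability > 1)
    stop("separability must lie in [0, 1]", call. = FALSE)
  structure(
    list(n_classes = n_classes, per_class_counts = per_class_counts,
         image_size = image_size, separability = separability,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic labeled image set
#'
#' Renders every image described by a [synthetic_spec()]. For class `k` the
#' image is a neutral field (0.5) plus, scaled by `separability`: a global
#' shift toward the class hue, an oriented sinusoid with class-specific
#' frequency and a random per-image phase, and an elliptical cap blob with
#' class-specific eccentricity at a random position/orientation; plus a
#' class-independent illumination offset and Gaussian pixel noise scaled by
#' `1 - separability`. Pixel values are clipped to `[0, 1]`. Output is
#' bit-reproducible for a fixed spec (including seed).
#'
#' @param spec a [synthetic_spec()].
#' @return An [image_set] whose per-class counts match `spec` exactly, with
#'   no split tags assigned.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$n_classes
  s <- spec$image_size
  sep <- spec$separability
  n_total <- sum(spec$per_class_counts)
  images <- array(0, c(s, s, 3L, n_total))
  labels <- rep(seq_len(k), times = spec$per_class_counts)

  # pixel coordinate grids in [0, 1]
  u <- (seq_len(s) - 0.5) / s
  gx <- matrix(u, s, s, byrow = TRUE)   # column coordinate
  gy <- matrix(u, s, s)                 # row coordinate

  with_local_seed(spec$seed, {
    idx <- 0L
    for (cls in seq_len(k)) {
      hue <- (cls - 1) / k
      col_k <- hsv_to_rgb_num(hue, 0.7, 0.65)      # class base color
      freq <- 2 + cls                              # cycles per image
      orient <- pi * (cls - 1) / k
      ecc <- if (k > 1) (cls - 1) / (k - 1) else 0 # 0 = circle
      ratio <- 1 + 3 * ecc                         # blob axis ratio
      proj <- gx * cos(orient) + gy * sin(orient)
      for (img in seq_len(spec$per_class_counts[cls])) {
        idx <- idx + 1L
        phase <- stats::runif(1, 0, 2 * pi)
        ctr <- stats::runif(2, 0.35, 0.65)
        bang <- stats::runif(1, 0, pi)
        illum <- stats::rnorm(1, 0, 0.05)
        tex <- 0.15 * sin(2 * pi * freq * proj + phase)
        dx <- gx - ctr[1]; dy <- gy - ctr[2]
        a <- 0.16 * sqrt(ratio); b <- 0.16 / sqrt(ratio)
        uu <- dx * cos(bang) + dy * sin(bang)
        vv <- -dx * sin(bang) + dy * cos(bang)
        blob <- exp(-((uu / a)^2 + (vv / b)^2))
        for (ch in 1:3) {
          sig <- 0.8 * (col_k[ch] - 0.5) + tex + 0.35 * blob * (col_k[ch] - 0.2)
          plane <- 0.5 + illum + sep * sig
          if (sep < 1)
            plane <- plane + (1 - sep) * matrix(stats::rnorm(s * s, 0, 0.15), s, s)
          images[, , ch, idx] <- pmin(pmax(plane, 0), 1)
        }
      }
    }
  })
  image_set(images, labels)
}

#' Stratified train/test split
#'
#' Tags each image as train or test with a per-class deterministic rule:
#' class `c` with `n_c` images contributes exactly `floor(train_frac * n_c)`
#' training images; the assignment within the class is a seeded random
#' permutation. Every image ends up in exactly one of the two splits.
#'
#' @param data an [image_set].
#' @param train_frac fraction of each class assigned to training,
#'   in `(0, 1)` (default 0.7).
#' @param seed integer RNG seed driving the within-class permutations.
#' @return The `image_set` with `split` tags filled in.
#' @export
split_stratified <- function(data, train_frac = 0.7, seed = 1) {
  stopifnot(inherits(data, "image_set"))
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly between 0 and 1", call. = FALSE)
  counts <- table(data$labels)
  if (any(counts < 2))
    stop("every class needs at least 2 images to be split", call. = FALSE)
  split <- rep(NA_character_, length(data$labels))
  with_local_seed(seed, {
    for (cls in sort(unique(data$labels))) {
      pos <- which(data$labels == cls)
      n_train <- floor(train_frac * length(pos))
      perm <- sample(pos)
      split[perm[seq_len(n_train)]] <- "train"
      split[perm[-seq_len(n_train)]] <- "test"
    }
  })
  data$split <- split
  data
}

#' Write an image set as a class-per-directory PNG tree
#'
#' Creates `root/<class_name>/<idx>.png` for every image, the same layout
#' [read_image_tree()] consumes. PNG export quantizes pixel values to 8 bits.
#'
#' @param data an [image_set].
#' @param root directory to create the tree under.
#' @return `root`, invisibly.
#' @export
write_image_tree <- function(data, root) {
  stopifnot(inherits(data, "image_set"))
  for (cls in seq_along(data$class_names)) {
    dir.create(file.path(root, data$class_names[cls]),
               recursive = TRUE, showWarnings = FALSE)
  }
  counter <- integer(length(data$class_names))
  for (i in seq_along(data$labels)) {
    cls <- data$labels[i]
    counter[cls] <- counter[cls] + 1L
    path <- file.path(root, data$class_names[cls],
                      sprintf("%04d.png", counter[cls]))
    # EBImage stores images x (width) first; our arrays are row (y) first
    img <- EBImage::Image(aperm(data$images[, , , i], c(2, 1, 3)),
                          colormode = "Color")
    EBImage::writeImage(img, path)
  }
  invisible(root)
}

# numeric HSV -> RGB (h, s, v scalars or equal-length vectors; h in [0,1))
hsv_to_rgb_num <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  c(r, g, b)
}

# numeric RGB -> HSV on 3 x n matrices (used by color jitter)
rgb_to_hsv_num <- function(rgb) {
  mx <- pmax(rgb[1, ], rgb[2, ], rgb[3, ])
  mn <- pmin(rgb[1, ], rgb[2, ], rgb[3, ])
  d <- mx - mn
  h <- numeric(length(mx))
  nz <- d > 0
  r <- rgb[1, ]; g <- rgb[2, ]; b <- rgb[3, ]
  hr <- nz & mx == r
  hg <- nz & !hr & mx == g
  hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / d[hr]) %% 6
  h[hg] <- (b[hg] - r[hg]) / d[hg] + 2
  h[hb] <- (r[hb] - g[hb]) / d[hb] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  rbind(h, s, mx)
}
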
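#' Labeled image set
#'
#' Container for a stack of RGB images with integer class labels and
#' train/test split tags. Images are stored as a single `H x W x 3 x N`
#' numeric array with values in `[0, 1]`.
#'
#' @param images numeric array of dimension `H x W x 3 x N` with values in
#'   `[0, 1]`.
#' @param labels integer vector of length `N`, class labels in `1..K`.
#' @param split character vector of length `N` with entries `"train"` or
#'   `"test"`, or `NA` when the set has not been split yet.
#' @param class_names optional character vector of length `K` naming the
#'   classes (used when writing/reading image trees).
#'
#' @return An object of class `image_set`.
#' @export
image_set <- function(images, labels, split = NULL, class_names = NULL) {
  if (!is.array(images) || length(dim(images)) != 4L || dim(images)[3] != 3L)
    stop("`images` must be an H x W x 3 x N array", call. = FALSE)
  n <- dim(images)[4]
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("length(labels) must equal the number of images", call. = FALSE)
  if (any(is.na(labels)) || any(labels < 1L))
    stop("labels must be integers in 1..K", call. = FALSE)
  k <- max(labels)
  if (is.null(split)) split <- rep(NA_character_, n)
  if (length(split) != n)
    stop("length(split) must equal the number of images", call. = FALSE)
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(k))
  structure(
    list(images = images, labels = labels, split = as.character(split),
         class_names = as.character(class_names)),
    class = "image_set"
  )
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_set> %d images, %dx%d px, %d classes\n",
              d[4], d[1], d[2], length(x$class_names)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names)))
  cat("  per-class counts:", paste(as.integer(tab), collapse = ", "), "\n")
  if (!all(is.na(x$split)))
    cat("  split:", sum(x$split == "train", na.rm = TRUE), "train /",
        sum(x$split == "test", na.rm = TRUE), "test\n")
  invisible(x)
}

#' @export
length.image_set <- function(x) dim(x$images)[4]

#' Subset an image set
#'
#' @param x an [image_set].
#' @param i index vector of images to keep.
#' @param ... unused.
#' @return An `image_set` with the selected images.
#' @export
`[.image_set` <- function(x, i, ...) {
  image_set(x$images[, , , i, drop = FALSE], x$labels[i], x$split[i],
            x$class_names)
}

#' Extract the train or test portion of a split image set
#'
#' @param data an [image_set] that has been through [split_stratified()].
#' @param which `"train"` or `"test"`.
#' @return An `image_set` containing only the requested portion.
#' @export
subset_split <- function(data, which = c("train", "test")) {
  which <- match.arg(which)
  if (all(is.na(data$split)))
    stop("image set has no split tags; call split_stratified() first",
         call. = FALSE)
  data[data$split == which]
}

# Local, restore-on-exit RNG scope so seeded operations do not disturb the
# caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
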
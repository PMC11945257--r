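# Small in-code fixtures shared across test files.

tiny_set <- function(n_classes = 3, per_class = 10, size = 16,
                     separability = 1, seed = 1) {
  generate_dataset(synthetic_spec(
    n_classes = n_classes, per_class_counts = rep(per_class, n_classes),
    image_size = size, separability = separability, seed = seed))
}

random_cm <- function(k = 4, n = 200, seed = 1, strength = 2) {
  set.seed(seed)
  actual <- sample(k, n, replace = TRUE)
  predicted <- ifelse(stats::runif(n) < strength / (strength + 1),
                      actual, sample(k, n, replace = TRUE))
  confusion_matrix(actual, predicted, k)
}

# Mean-RGB nearest-centroid classifier: the independent oracle for whether
# a synthetic dataset is learnable at all.
centroid_accuracy <- function(data, train_frac = 0.7, seed = 1) {
  data <- split_stratified(data, train_frac, seed)
  mean_rgb <- t(apply(data$images, 4, function(im) {
    c(mean(im[, , 1]), mean(im[, , 2]), mean(im[, , 3]))
  }))
  tr <- data$split == "train"
  classes <- sort(unique(data$labels))
  centroids <- t(vapply(classes, function(cl) {
    colMeans(mean_rgb[tr & data$labels == cl, , drop = FALSE])
  }, numeric(3)))
  d2 <- outer(rowSums(mean_rgb^2), rep(1, nrow(centroids))) -
    2 * mean_rgb %*% t(centroids) +
    outer(rep(1, nrow(mean_rgb)), rowSums(centroids^2))
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred[!tr] == data$labels[!tr])
}
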
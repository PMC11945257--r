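#' Experiment configuration
#'
#' Bundles everything a seeded end-to-end run needs: the data source, the
#' model variant, the split fraction, and the sub-module settings.
#'
#' Variants and their compositions:
#' * `"cnn"` — train the CNN, classify with its own softmax head.
#' * `"cnn_som"` — train the CNN, extract block-4 features, fit a
#'   supervised SOM on them, predict by BMU label.
#' * `"cnn_kan"` — train the CNN, extract pooled 256-d features, train the
#'   sine-activation head on them (CNN frozen).
#' * `"ensemble"` — extract features with two backbone callables,
#'   concatenate, train the fully connected classification block.
#' * `"backbone_som"` — extract features with backbone A, fit a supervised
#'   SOM on them (10 x 10, 1000 iterations by default).
#'
#' @param data a [synthetic_spec()] or a path to a class-per-directory
#'   image tree.
#' @param variant one of `"cnn"`, `"cnn_som"`, `"cnn_kan"`, `"ensemble"`,
#'   `"backbone_som"`.
#' @param train_frac training fraction for the stratified split
#'   (default 0.7).
#' @param seed master seed; drives the split and, unless overridden in the
#'   sub-configs, all training randomness.
#' @param cnn a [cnn_config()]; its `input_size` must match the data.
#' @param train a [train_config()].
#' @param som named list of SOM settings (`rows`, `cols`, `sigma0`,
#'   `alpha0`, `n_iter`, `decay`); defaults 20 x 20, 1.0, 0.5, 5000
#'   (10 x 10 / 1000 for `backbone_som`).
#' @param kan named list of head settings (`hidden`), default 128.
#' @param ensemble an [ensemble_config()].
#' @param backbones list of two feature-extractor functions for the
#'   ensemble / backbone variants; defaults to seeded [backbone_stub()]s
#'   of widths 768 and 2048.
#' @param augment an [augmentation_policy()] applied during CNN training,
#'   or `NULL` for none (the default here; pass a policy for the full
#'   augmented regime).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(data = synthetic_spec(),
                              variant = c("cnn", "cnn_som", "cnn_kan",
                                          "ensemble", "backbone_som"),
                              train_frac = 0.7, seed = 1,
                              cnn = NULL, train = train_config(),
                              som = list(), kan = list(hidden = 128),
                              ensemble = ensemble_config(),
                              backbones = NULL, augment = NULL) {
  variant <- match.arg(variant)
  som_defaults <- if (variant == "backbone_som")
    list(rows = 10, cols = 10, sigma0 = 1.0, alpha0 = 0.5, n_iter = 1000,
         decay = "exponential")
  else
    list(rows = 20, cols = 20, sigma0 = 1.0, alpha0 = 0.5, n_iter = 5000,
         decay = "exponential")
  som <- utils::modifyList(som_defaults, som)
  structure(
    list(data = data, variant = variant, train_frac = train_frac,
         seed = as.integer(seed), cnn = cnn, train = train, som = som,
         kan = kan, ensemble = ensemble, backbones = backbones,
         augment = augment),
    class = "experiment_config"
  )
}

#' Read a class-per-directory image tree
#'
#' Reads `root/<class>/<image>` (PNG/JPEG/TIFF), assigns labels `1..K` by
#' lexicographic directory order, and resizes every image to
#' `image_size x image_size`.
#'
#' @param root directory containing one subdirectory per class.
#' @param image_size target side length in pixels (default 224).
#' @return An [image_set] with `class_names` set to the directory names.
#' @export
read_image_tree <- function(root, image_size = 224) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  dirs <- sort(list.dirs(root, recursive = FALSE, full.names = TRUE))
  if (length(dirs) < 2L)
    stop("need at least 2 class subdirectories under ", root, call. = FALSE)
  files <- lapply(dirs, function(d) sort(list.files(d, full.names = TRUE,
    pattern = "\\.(png|jpg|jpeg|tif|tiff)$", ignore.case = TRUE)))
  if (any(lengths(files) == 0L))
    stop("class directory without decodable images: ",
         basename(dirs[lengths(files) == 0L][1]), call. = FALSE)
  n <- sum(lengths(files))
  images <- array(0, c(image_size, image_size, 3L, n))
  labels <- integer(n)
  idx <- 0L
  for (cls in seq_along(dirs)) {
    for (f in files[[cls]]) {
      idx <- idx + 1L
      img <- EBImage::readImage(f)
      dat <- EBImage::imageData(img)
      if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3), c(dim(dat), 3L))
      if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]
      if (dim(dat)[1] != image_size || dim(dat)[2] != image_size)
        dat <- EBImage::imageData(EBImage::resize(
          EBImage::Image(dat, colormode = "Color"),
          w = image_size, h = image_size))
      images[, , , idx] <- aperm(dat, c(2, 1, 3))   # x,y -> row,col
      labels[idx] <- cls
    }
  }
  image_set(images, labels, class_names = basename(dirs))
}

#' Run an end-to-end experiment
#'
#' Generates or loads the data, makes the stratified split, trains the
#' requested variant on the training portion, predicts the held-out test
#' portion, and evaluates all macro metrics (including the one-vs-rest
#' AUC). Fully deterministic for a fixed config.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory: writes the confusion matrix
#'   (`confusion.csv`), the metric report (`metrics.json` / `metrics.csv`),
#'   per-image predictions (`predictions.csv`) and the resolved run log
#'   (`run_log.yaml`).
#' @param verbose print per-epoch training progress.
#' @return A list of class `experiment_result`: `report` (one-row metric
#'   tibble), `confusion`, `predictions` tibble, the fitted component
#'   models, the split sizes and the resolved config.
#' @export
run_experiment <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  variants <- c("cnn", "cnn_som", "cnn_kan", "ensemble", "backbone_som")
  if (!cfg$variant %in% variants)
    stop("invalid variant; valid names: ", paste(variants, collapse = ", "),
         call. = FALSE)

  data <- if (inherits(cfg$data, "synthetic_spec")) generate_dataset(cfg$data)
          else if (inherits(cfg$data, "image_set")) cfg$data
          else read_image_tree(cfg$data)
  data <- split_stratified(data, cfg$train_frac, cfg$seed)
  train_set <- subset_split(data, "train")
  test_set <- subset_split(data, "test")
  k <- length(unique(data$labels))
  img_size <- dim(data$images)[1]

  cnn_cfg <- cfg$cnn
  if (is.null(cnn_cfg) && cfg$variant %in% c("cnn", "cnn_som", "cnn_kan"))
    cnn_cfg <- cnn_config(input_size = img_size, n_classes = k)
  models <- list()

  if (cfg$variant %in% c("cnn", "cnn_som", "cnn_kan")) {
    model <- build_cnn(cnn_cfg, seed = cfg$seed)
    model <- train_cnn(model, data, cfg$train, policy = cfg$augment,
                       verbose = verbose)
    models$cnn <- model
  }

  if (cfg$variant %in% c("ensemble", "backbone_som")) {
    backbones <- cfg$backbones
    if (is.null(backbones))
      backbones <- list(backbone_stub(768, seed = cfg$seed),
                        backbone_stub(2048, seed = cfg$seed + 1L))
  }

  scores <- NULL
  if (cfg$variant == "cnn") {
    probs <- predict(models$cnn, test_set, type = "prob")
    pred <- max.col(probs, ties.method = "first")
    scores <- probs
  } else if (cfg$variant == "cnn_som") {
    ftr <- extract_block4_features(models$cnn, train_set)
    fte <- extract_block4_features(models$cnn, test_set)
    som <- som_fit(ftr, train_set$labels,
                   rows = cfg$som$rows, cols = cfg$som$cols,
                   sigma0 = cfg$som$sigma0, alpha0 = cfg$som$alpha0,
                   n_iter = cfg$som$n_iter, decay = cfg$som$decay,
                   seed = cfg$seed)
    models$som <- som
    pred <- predict(som, fte)
    scores <- class_scores(som, fte)
  } else if (cfg$variant == "cnn_kan") {
    ftr <- extract_gap_features(models$cnn, train_set)
    fte <- extract_gap_features(models$cnn, test_set)
    kan <- train_kan(ftr, train_set$labels, cfg$train,
                     hidden = cfg$kan$hidden)
    models$kan <- kan
    logits <- kan_forward(fte, kan)
    pred <- max.col(logits, ties.method = "first")
    scores <- softmax_probs(logits)
  } else if (cfg$variant == "ensemble") {
    fa_tr <- backbones[[1]](train_set); fb_tr <- backbones[[2]](train_set)
    fa_te <- backbones[[1]](test_set); fb_te <- backbones[[2]](test_set)
    vtr <- concat_features(fa_tr, fb_tr)
    vte <- concat_features(fa_te, fb_te)
    ecfg <- ensemble_config(dim_a = ncol(fa_tr), dim_b = ncol(fb_tr),
                            hidden = cfg$ensemble$hidden,
                            dropout = cfg$ensemble$dropout,
                            n_classes = k)
    head <- train_ensemble(vtr, train_set$labels, cfg$train, ecfg)
    models$ensemble <- head
    logits <- ensemble_forward(vte, head)
    pred <- max.col(logits, ties.method = "first")
    scores <- softmax_probs(logits)
  } else { # backbone_som
    ftr <- backbones[[1]](train_set)
    fte <- backbones[[1]](test_set)
    som <- som_fit(ftr, train_set$labels,
                   rows = cfg$som$rows, cols = cfg$som$cols,
                   sigma0 = cfg$som$sigma0, alpha0 = cfg$som$alpha0,
                   n_iter = cfg$som$n_iter, decay = cfg$som$decay,
                   seed = cfg$seed)
    models$som <- som
    pred <- predict(som, fte)
    scores <- class_scores(som, fte)
  }

  cm <- confusion_matrix(test_set$labels, pred, n_classes = k)
  report <- evaluate_predictions(test_set$labels, pred, scores,
                                 n_classes = k)
  predictions <- tibble::tibble(actual = test_set$labels, predicted = pred)
  result <- structure(
    list(report = report, confusion = cm, predictions = predictions,
         models = models,
         n_train = length(train_set$labels), n_test = length(test_set$labels),
         variant = cfg$variant, config = cfg),
    class = "experiment_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_confusion_csv(cm, file.path(out_dir, "confusion.csv"))
    jsonlite::write_json(as.list(report), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(report, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    yaml::write_yaml(resolve_config(cfg, k, img_size),
                     file.path(out_dir, "run_log.yaml"))
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> variant %s: %d train / %d test\n",
              x$variant, x$n_train, x$n_test))
  print(x$report)
  invisible(x)
}

# Serializable summary of all resolved settings and seeds for the run log.
resolve_config <- function(cfg, k, img_size) {
  list(
    variant = cfg$variant,
    seed = cfg$seed,
    train_frac = cfg$train_frac,
    n_classes = k,
    image_size = img_size,
    class_label_order = "lexicographic directory names -> labels 1..K",
    data = if (inherits(cfg$data, "synthetic_spec"))
      cfg$data[c("n_classes", "per_class_counts", "image_size",
                 "separability", "seed")]
      else as.character(cfg$data),
    train = unclass(cfg$train),
    som = cfg$som,
    kan = cfg$kan,
    augment = if (is.null(cfg$augment)) "none" else unclass(cfg$augment)
  )
}

#' Read an experiment configuration from YAML
#'
#' Accepts the keys of [experiment_config()]; `data` may be a path or a
#' `synthetic:` block with [synthetic_spec()] fields; `train` and `som`
#' blocks override the defaults field by field.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  data <- if (!is.null(y$synthetic))
    do.call(synthetic_spec, y$synthetic)
  else if (!is.null(y$data)) y$data
  else synthetic_spec()
  train <- do.call(train_config,
                   utils::modifyList(list(), as.list(y$train)))
  experiment_config(
    data = data,
    variant = if (is.null(y$variant)) "cnn_som" else y$variant,
    train_frac = if (is.null(y$train_frac)) 0.7 else y$train_frac,
    seed = if (is.null(y$seed)) 1L else y$seed,
    train = train,
    som = as.list(y$som),
    kan = if (is.null(y$kan)) list(hidden = 128) else as.list(y$kan),
    augment = if (isTRUE(y$augment)) augmentation_policy() else NULL
  )
}
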
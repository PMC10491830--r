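# Trainable per-pixel classification: annotated pixels (colonized fungal
# structures, uncolonized root tissue, background) are described by the
# 25-channel feature bank and fed to a random forest; the trained model
# labels every pixel of new images, yielding the areas behind the ml-index.

CLASS_LEVELS <- c("colonized", "root_tissue", "background")
MODEL_VERSION <- "rootquant_model_v1"

#' Bundle annotated images for training
#'
#' A label mask assigns each pixel one of: 0 = unlabeled, 1 = colonized,
#' 2 = root_tissue, 3 = background. Only labelled pixels enter the training
#' set; sparse scribbles are the expected annotation style.
#'
#' @param images list of grayscale matrices.
#' @param label_masks list of integer matrices (same geometries) with values
#'   in 0..3.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(images, label_masks) {
  if (length(images) == 0L || length(images) != length(label_masks))
    stop_validation("`images` and `label_masks` must be non-empty lists of equal length")
  for (i in seq_along(images)) {
    img <- as_gray_matrix(images[[i]], sprintf("images[[%d]]", i))
    lm <- label_masks[[i]]
    if (!is.matrix(lm) || !all(lm %in% 0:3))
      stop_validation("label mask %d must be a matrix with values in 0..3", i)
    check_same_geometry(img, lm, sprintf("image/label pair %d", i))
  }
  counts <- integer(3L)
  for (lm in label_masks)
    counts <- counts + tabulate(lm[lm > 0L], nbins = 3L)
  structure(list(images = lapply(images, as_gray_matrix),
                 label_masks = label_masks,
                 class_counts = setNames(counts, CLASS_LEVELS)),
            class = "annotation_set")
}

#' Rasterize annotations from a synthetic scene's ground truth
#'
#' Samples up to `n_per_class` pixels per class from the scene's true masks
#' — the synthetic stand-in for an operator scribbling on fungal structures,
#' clean root tissue and background.
#'
#' @param scene a [generate_scene()] result.
#' @param n_per_class pixels sampled per class.
#' @param gray_method grayscale conversion for the scene image.
#' @param seed RNG seed for the pixel sampling.
#' @return list with `image` (grayscale matrix) and `labels` (0..3 matrix).
#' @export
annotate_from_scene <- function(scene, n_per_class = 200L,
                                gray_method = "luminance", seed = 1L) {
  if (!inherits(scene, "synthetic_scene"))
    stop_validation("`scene` must come from generate_scene()")
  img <- to_grayscale(scene$image, gray_method)
  root <- scene$root_mask != 0
  col <- scene$colonized_mask != 0
  pools <- list(colonized = which(col),
                root_tissue = which(root & !col),
                background = which(!root))
  labels <- matrix(0L, nrow(img), ncol(img))
  with_seed(seed, {
    for (k in seq_along(pools)) {
      p <- pools[[k]]
      if (length(p) == 0L) next
      take <- p[sample.int(length(p), min(n_per_class, length(p)))]
      labels[take] <- k
    }
  })
  list(image = unclass(img), labels = labels)
}

#' Build the training matrix from annotations
#'
#' @param annotations an [annotation_set()].
#' @param cfg a [feature_config()].
#' @return list with `features` (n x 25 matrix), `labels` (factor over the
#'   class levels), `config`, and `class_balance` (per-class row counts).
#' @export
build_training_set <- function(annotations, cfg = feature_config()) {
  if (!inherits(annotations, "annotation_set"))
    stop_validation("`annotations` must come from annotation_set()")
  if (sum(annotations$class_counts) == 0L)
    stop_validation("annotation set contains no labelled pixels")
  if (sum(annotations$class_counts > 0L) < 2L)
    stop_validation("training needs >= 2 annotated classes, got %d",
                    sum(annotations$class_counts > 0L))
  feats <- list(); labs <- list()
  for (i in seq_along(annotations$images)) {
    lm <- annotations$label_masks[[i]]
    idx <- which(lm > 0L)
    if (length(idx) == 0L) next
    stack <- compute_feature_stack(annotations$images[[i]], cfg)
    coords <- cbind((idx - 1L) %% nrow(lm) + 1L,
                    (idx - 1L) %/% nrow(lm) + 1L)
    feats[[length(feats) + 1L]] <- sample_features(stack, coords)
    labs[[length(labs) + 1L]] <- CLASS_LEVELS[lm[idx]]
  }
  features <- do.call(rbind, feats)
  labels <- factor(unlist(labs), levels = CLASS_LEVELS)
  list(features = features, labels = droplevels(labels), config = cfg,
       class_balance = table(droplevels(labels)))
}

#' Train the per-pixel random forest
#'
#' @param training output of [build_training_set()].
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth (`NULL` = unlimited; translated to a
#'   terminal-node cap of `2^max_depth`).
#' @param seed RNG seed; training is deterministic given the seed.
#' @return Object of class `pixel_model`: the forest, the feature
#'   configuration (with hash), class levels and training metadata
#'   (including out-of-bag accuracy).
#' @export
train_pixel_model <- function(training, n_trees = 100L, max_depth = NULL,
                              seed = 1L) {
  if (!is.list(training) || is.null(training$features) ||
      is.null(training$labels))
    stop_validation("`training` must come from build_training_set()")
  x <- training$features
  y <- droplevels(training$labels)
  if (nrow(x) == 0L) stop_validation("empty training set")
  if (nlevels(y) < 2L) stop_validation("training needs >= 2 classes")
  if (all(apply(x, 2, function(v) length(unique(v)) == 1L)))
    warning("all feature columns are constant; the model cannot discriminate")
  maxnodes <- if (is.null(max_depth)) NULL else as.integer(2^max_depth)
  forest <- with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = n_trees,
                               maxnodes = maxnodes))
  oob <- 1 - mean(forest$err.rate[n_trees, "OOB"])
  structure(list(
    forest = forest,
    config = training$config,
    config_hash = feature_config_hash(training$config),
    classes = levels(y),
    metadata = list(n_training_pixels = nrow(x),
                    class_balance = as.list(table(y)),
                    n_trees = n_trees, max_depth = max_depth, seed = seed,
                    oob_accuracy = unname(oob)),
    version = MODEL_VERSION
  ), class = "pixel_model")
}

#' @export
print.pixel_model <- function(x, ...) {
  cat(sprintf(
    "pixel_model (%s): %d trees, %d training px, OOB accuracy %.3f\n",
    paste(x$classes, collapse = "/"), x$metadata$n_trees,
    x$metadata$n_training_pixels, x$metadata$oob_accuracy))
  invisible(x)
}

#' Label every pixel of an image
#'
#' Computes the feature stack with the model's own configuration (a
#' precomputed stack is refused unless its configuration hash matches) and
#' assigns each pixel the class with the highest forest vote, ties broken
#' toward the class listed first in the model's class list.
#'
#' @param model a [train_pixel_model()] result.
#' @param img grayscale matrix, or a precomputed `feature_stack`.
#' @return Object of class `label_map`: integer `H x W` matrix (indices into
#'   `attr(, "classes")`) with per-class pixel `areas` attached.
#' @export
predict_pixels <- function(model, img) {
  if (!inherits(model, "pixel_model"))
    stop_validation("`model` must be a pixel_model")
  if (inherits(img, "feature_stack")) {
    if (!identical(attr(img, "config_hash"), model$config_hash))
      stop_validation(
        "feature configuration mismatch: stack %s vs model %s",
        attr(img, "config_hash"), model$config_hash)
    stack <- img
  } else {
    stack <- compute_feature_stack(as_gray_matrix(img), model$config)
  }
  d <- dim(stack)
  flat <- matrix(unclass(stack), d[1] * d[2], d[3])
  colnames(flat) <- dimnames(stack)[[3]]
  votes <- predict(model$forest, flat, type = "vote", norm.votes = FALSE)
  votes <- votes[, model$classes, drop = FALSE]  # tie-break by class order
  lab <- max.col(votes, ties.method = "first")
  out <- matrix(as.integer(lab), d[1], d[2])
  areas <- setNames(tabulate(lab, nbins = length(model$classes)),
                    model$classes)
  structure(out, classes = model$classes, areas = areas,
            class = c("label_map", class(out)))
}

#' Per-class pixel areas of a label map
#' @param map a [predict_pixels()] result.
#' @return Named integer vector summing to `H * W`.
#' @export
label_areas <- function(map) attr(map, "areas")

#' ml-index of a labelled image
#'
#' `100 * colonized / (colonized + non-colonized)`. By default the
#' denominator is restricted to root tissue (colonized + root_tissue
#' pixels); set `include_background = TRUE` to count background pixels as
#' non-colonized area as well.
#'
#' @param map a [predict_pixels()] result.
#' @param include_background include background pixels in the denominator.
#' @param image_id identifier recorded in the result.
#' @return A [colonization_measure()] with `method = "ml"`.
#' @export
measure_ml <- function(map, include_background = FALSE,
                       image_id = "image") {
  a <- label_areas(map)
  colonized <- a[["colonized"]]
  non <- a[["root_tissue"]] +
    if (include_background) a[["background"]] else 0L
  colonization_measure(image_id, colonized, colonized + non, method = "ml")
}

#' Save / load a trained pixel model
#'
#' The archive stores the forest, the feature configuration and metadata;
#' loading verifies the format version and reproduces predictions exactly.
#'
#' @param model a `pixel_model`.
#' @param path file path (`.rds` archive).
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "pixel_model"))
    stop_validation("`model` must be a pixel_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_io("model file does not exist: %s", path)
  m <- readRDS(path)
  if (!inherits(m, "pixel_model") || !identical(m$version, MODEL_VERSION))
    stop_io("not a compatible model file (expected version %s): %s",
            MODEL_VERSION, path)
  m
}

#' Export / import a training reference folder
#'
#' Writes the annotated images and label masks in a shareable layout
#' (`images/img_NNN.png`, `labels/img_NNN.png`, `config.yaml`), so a
#' training set can be published and re-used verbatim by other groups.
#' Label PNGs encode the raw class index (0..3) in the low intensity bits.
#'
#' @param annotations an [annotation_set()].
#' @param path folder to create.
#' @param cfg the [feature_config()] to record.
#' @return `export_training_folder`: `path`, invisibly;
#'   `import_training_folder`: an [annotation_set()] (with the stored
#'   config as attribute `config`).
#' @export
export_training_folder <- function(annotations, path,
                                   cfg = feature_config()) {
  if (!inherits(annotations, "annotation_set"))
    stop_validation("`annotations` must come from annotation_set()")
  if (sum(annotations$class_counts) == 0L)
    stop_validation("refusing to export an empty annotation set")
  dir.create(file.path(path, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(path, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_along(annotations$images)) {
    nm <- sprintf("img_%03d.png", i)
    write_image(annotations$images[[i]], file.path(path, "images", nm))
    png::writePNG(annotations$label_masks[[i]] / 255,
                  file.path(path, "labels", nm))
  }
  yaml::write_yaml(list(format = "rootquant_training_v1",
                        classes = CLASS_LEVELS,
                        features = unclass(cfg)),
                   file.path(path, "config.yaml"),
                   precision = 17L)  # angles like pi/4 must round-trip exactly
  invisible(path)
}

#' @rdname export_training_folder
#' @export
import_training_folder <- function(path) {
  cfg_file <- file.path(path, "config.yaml")
  if (!file.exists(cfg_file))
    stop_io("not a training folder (missing config.yaml): %s", path)
  meta <- yaml::read_yaml(cfg_file)
  cfg <- do.call(feature_config, meta$features)
  imgs <- sort(list.files(file.path(path, "images"), pattern = "\\.png$",
                          full.names = TRUE))
  if (length(imgs) == 0L) stop_io("training folder has no images: %s", path)
  images <- list(); labels <- list()
  for (i in seq_along(imgs)) {
    images[[i]] <- unclass(to_grayscale(read_image(imgs[i]), "red"))
    lab_path <- file.path(path, "labels", basename(imgs[i]))
    if (!file.exists(lab_path))
      stop_io("missing label mask for %s", basename(imgs[i]))
    labels[[i]] <- matrix(as.integer(round(png::readPNG(lab_path) * 255)),
                          nrow = nrow(images[[i]]))
  }
  ann <- annotation_set(images, labels)
  attr(ann, "config") <- cfg
  ann
}
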
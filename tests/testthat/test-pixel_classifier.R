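test_that("training rows are conserved and degenerate annotation is refused", {
  sc <- generate_scene(small_scene_params(target = 0.3, seed = 6))
  ann1 <- annotate_from_scene(sc, n_per_class = 40, seed = 2)
  ann <- annotation_set(list(ann1$image), list(ann1$labels))
  tr <- build_training_set(ann)
  expect_equal(nrow(tr$features), sum(ann1$labels > 0))
  expect_equal(ncol(tr$features), 25L)
  expect_equal(length(tr$labels), nrow(tr$features))

  # single-class annotation -> explicit error
  only_bg <- ann1$labels; only_bg[only_bg != 3L] <- 0L
  expect_error(build_training_set(annotation_set(list(ann1$image),
                                                 list(only_bg))),
               class = "rootquant_validation_error")
  # zero annotated pixels -> error, not empty success
  expect_error(build_training_set(annotation_set(list(ann1$image),
                                                 list(ann1$labels * 0L))),
               class = "rootquant_validation_error")
})

test_that("scene-derived features separate colonized from background by intensity", {
  sc <- generate_scene(small_scene_params(target = 0.3, seed = 10))
  a <- annotate_from_scene(sc, n_per_class = 60, seed = 4)
  tr <- build_training_set(annotation_set(list(a$image), list(a$labels)))
  g1 <- tr$features[, "gaussian_s1"]
  expect_lt(max(g1[tr$labels == "colonized"]),
            min(g1[tr$labels == "background"]))
})

test_that("training is deterministic: same data + seed gives byte-identical models", {
  ann <- scene_annotations(2, function(s) small_scene_params(0.3, seed = s),
                           n_per_class = 60)
  tr <- build_training_set(ann)
  p1 <- withr::local_tempfile(fileext = ".rds")
  p2 <- withr::local_tempfile(fileext = ".rds")
  save_model(train_pixel_model(tr, n_trees = 25, seed = 99), p1)
  save_model(train_pixel_model(tr, n_trees = 25, seed = 99), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("a separable two-class problem is learned perfectly", {
  set.seed(5)
  x <- rbind(matrix(rnorm(50 * 25, 0), 50, 25),
             matrix(rnorm(50 * 25, 8), 50, 25))
  colnames(x) <- dimnames(compute_feature_stack(flat_gray(0, 9, 9)))[[3]]
  tr <- list(features = x,
             labels = factor(rep(c("colonized", "background"), each = 50),
                             levels = c("colonized", "root_tissue",
                                        "background")),
             config = feature_config())
  model <- train_pixel_model(tr, n_trees = 50, seed = 1)
  fitted_cls <- predict(model$forest, x)
  expect_equal(mean(as.character(fitted_cls) == as.character(tr$labels)), 1)
  expect_gt(model$metadata$oob_accuracy, 0.95)
})

test_that("label maps are total partitions and sane on training-like frames", {
  ann <- scene_annotations(3, function(s) small_scene_params(0.3, seed = s),
                           n_per_class = 80)
  model <- train_pixel_model(build_training_set(ann), n_trees = 40, seed = 3)
  # pure background frame at the scene background level
  bg <- flat_gray(250, 48, 48)
  map <- predict_pixels(model, bg)
  areas <- label_areas(map)
  expect_equal(sum(areas), 48 * 48)
  expect_gte(areas[["background"]] / sum(areas), 0.99)

  sc <- generate_scene(small_scene_params(target = 0.35, seed = 60))
  map2 <- predict_pixels(model, to_grayscale(sc$image))
  expect_equal(sum(label_areas(map2)), prod(sc$params$geometry))
})

test_that("prediction refuses a feature stack from a different configuration", {
  ann <- scene_annotations(2, function(s) small_scene_params(0.3, seed = s),
                           n_per_class = 50)
  model <- train_pixel_model(build_training_set(ann), n_trees = 20, seed = 2)
  other <- feature_config(hessian_sigma = 3)
  sc <- generate_scene(small_scene_params(target = 0.2, seed = 70))
  stack <- compute_feature_stack(to_grayscale(sc$image), other)
  expect_error(predict_pixels(model, stack),
               class = "rootquant_validation_error")
  # matching config works
  ok <- compute_feature_stack(to_grayscale(sc$image), model$config)
  expect_s3_class(predict_pixels(model, ok), "label_map")
})

test_that("save/load reproduces predictions exactly and checks the version", {
  ann <- scene_annotations(2, function(s) small_scene_params(0.3, seed = s),
                           n_per_class = 50)
  model <- train_pixel_model(build_training_set(ann), n_trees = 20, seed = 4)
  sc <- generate_scene(small_scene_params(target = 0.25, seed = 80))
  g <- to_grayscale(sc$image)
  before <- predict_pixels(model, g)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  after <- predict_pixels(load_model(path), g)
  expect_identical(unclass(before), unclass(after))

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(version = "other"), bad)
  expect_error(load_model(bad), class = "rootquant_io_error")
})

test_that("a training folder exports and re-imports to the same matrix", {
  ann <- scene_annotations(2, function(s) small_scene_params(0.3, seed = s),
                           n_per_class = 40)
  dir <- withr::local_tempdir()
  export_training_folder(ann, dir)
  back <- import_training_folder(dir)
  tr1 <- build_training_set(ann)
  tr2 <- build_training_set(back, attr(back, "config"))
  expect_equal(tr1$features, tr2$features)
  expect_equal(tr1$labels, tr2$labels)

  empty <- ann
  empty$class_counts[] <- 0L
  expect_error(export_training_folder(empty, withr::local_tempdir()),
               class = "rootquant_validation_error")
})

test_that("the ml-index recovers ground truth on clean sibling scenes", {
  ann <- scene_annotations(5, function(s)
    small_scene_params(0.3, seed = s), n_per_class = 100)
  model <- train_pixel_model(build_training_set(ann), n_trees = 60, seed = 9)
  for (tg in c(0.15, 0.4)) {
    sc <- generate_scene(small_scene_params(tg, seed = 300 + round(100 * tg)))
    m <- measure_ml(predict_pixels(model, to_grayscale(sc$image)),
                    image_id = "scene")
    expect_lte(abs(m$index_value - 100 * sc$true_fraction), 5)
  }
})
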
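test_that("the configuration is pinned to exactly 25 channels", {
  cfg <- feature_config()
  expect_error(feature_config(gaussian_sigmas = c(1, 2, 4)),
               class = "rootquant_validation_error")
  expect_error(feature_config(gaussian_sigmas = c(4, 2, 1, 8, 16)),
               class = "rootquant_validation_error")
  expect_error(feature_config(gabor_frequencies = c(0.1, 0.2)),
               class = "rootquant_validation_error")
  stack <- compute_feature_stack(flat_gray(7, 24, 24), cfg)
  expect_equal(dim(stack)[3], 25L)
  expect_equal(length(unique(dimnames(stack)[[3]])), 25L)
})

test_that("a flat field gives constant Gaussian and zero derivative channels", {
  stack <- compute_feature_stack(flat_gray(42, 40, 40))
  nm <- dimnames(stack)[[3]]
  for (ch in grep("^gaussian", nm))
    expect_equal(as.vector(stack[, , ch]), rep(42, 1600), tolerance = 1e-10)
  for (ch in c(grep("^sobel", nm), grep("^hessian_eig", nm)))
    expect_lt(max(abs(stack[, , ch])), 1e-8)
})

test_that("Gaussian channels match a brute-force convolution oracle", {
  set.seed(6)
  img <- matrix(runif(81, 0, 255), 9, 9)
  sigma <- 1
  r <- ceiling(3 * sigma)
  g1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  kern <- outer(g1, g1); kern <- kern / sum(kern)
  reflect <- function(i, n) {          # mirror without repeating the edge
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  expected <- matrix(0, 9, 9)
  for (i in 1:9) for (j in 1:9) {
    acc <- 0
    for (u in -r:r) for (v in -r:r)
      acc <- acc + kern[u + r + 1, v + r + 1] *
        img[reflect(i + u, 9), reflect(j + v, 9)]
    expected[i, j] <- acc
  }
  stack <- compute_feature_stack(img)
  expect_lt(max(abs(stack[, , "gaussian_s1"] - expected)), 1e-6)
})

test_that("Gaussian smoothing preserves the global mean under reflection", {
  expect_equal(mean(compute_feature_stack(flat_gray(99, 30, 30))[, , 1]), 99,
               tolerance = 1e-12)
  set.seed(23)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  stack <- compute_feature_stack(img)
  for (ch in 1:5)
    expect_lt(abs(mean(stack[, , ch]) - mean(img)) / mean(img), 1e-3)
})

test_that("the larger Hessian eigenvalue dominates everywhere", {
  sc <- generate_scene(small_scene_params(target = 0.3, seed = 11))
  stack <- compute_feature_stack(to_grayscale(sc$image))
  expect_true(all(stack[, , "hessian_eig1"] >= stack[, , "hessian_eig2"]))
})

test_that("a 90-degree rotation permutes the Gabor orientation channels", {
  set.seed(19)
  img <- flat_gray(200, 48, 48)
  img[, seq(4, 48, by = 8)] <- 60      # vertical stripes
  rot <- t(img)[ncol(img):1, ]         # rotate 90 degrees counterclockwise
  s0 <- compute_feature_stack(img)
  s90 <- compute_feature_stack(rot)
  core <- 17:32                        # stay away from boundary effects
  for (f in c(0.12, 0.25)) {
    a <- s0[core, core, sprintf("gabor_f%g_o0", f)]
    b <- s90[core, core, sprintf("gabor_f%g_o90", f)]
    # rotate the o0 response map to compare pixelwise with the o90 map
    a_rot <- t(s0[, , sprintf("gabor_f%g_o0", f)])[ncol(img):1, ][core, core]
    expect_lt(max(abs(a_rot - b)) / max(abs(a)), 1e-6)
  }
})

test_that("sample_features equals a per-pixel lookup loop", {
  sc <- generate_scene(small_scene_params(target = 0.2, seed = 8))
  stack <- compute_feature_stack(to_grayscale(sc$image))
  expect_equal(nrow(sample_features(stack, matrix(0L, 0, 2))), 0L)
  set.seed(3)
  coords <- cbind(sample(1:96, 10), sample(1:128, 10))
  got <- sample_features(stack, coords)
  for (i in 1:10) for (ch in 1:25)
    expect_identical(unname(got[i, ch]),
                     unname(stack[coords[i, 1], coords[i, 2], ch]))
  expect_error(sample_features(stack, rbind(coords, c(97, 1))),
               class = "rootquant_validation_error")
})
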
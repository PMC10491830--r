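# Per-pixel texture feature bank: each pixel of a grayscale micrograph is
# described by 25 filter responses — 5 Gaussian blurs, 5 Sobel gradient
# magnitudes of Gaussian blurs, 12 Gabor magnitudes (3 frequencies x 4
# orientations) and 3 Hessian features — the description vector consumed by
# the pixel classifier. All convolutions use reflective boundary padding.

#' Configuration of the 25-channel feature bank
#'
#' Defaults use octave-spaced scales spanning the width range of fungal
#' structures at low magnification (hyphae a few pixels wide, arbuscule
#' patches tens of pixels): sigmas 1-16 px, Gabor wavelengths 4-20 px. The
#' channel count is fixed by construction at 5 + 5 + 3*4 + 3 = 25.
#'
#' @param gaussian_sigmas 5 strictly increasing positive sigmas (px).
#' @param sobel_sigmas 5 strictly increasing positive sigmas (px).
#' @param gabor_frequencies 3 positive spatial frequencies (cycles/px).
#' @param gabor_orientations 4 angles in `[0, pi)` (radians).
#' @param hessian_sigma single positive smoothing sigma (px).
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(gaussian_sigmas = c(1, 2, 4, 8, 16),
                           sobel_sigmas = c(1, 2, 4, 8, 16),
                           gabor_frequencies = c(0.05, 0.12, 0.25),
                           gabor_orientations = c(0, pi / 4, pi / 2,
                                                  3 * pi / 4),
                           hessian_sigma = 2) {
  if (length(gaussian_sigmas) != 5L || any(gaussian_sigmas <= 0) ||
      is.unsorted(gaussian_sigmas, strictly = TRUE))
    stop_validation("`gaussian_sigmas` must be 5 strictly increasing positive values")
  if (length(sobel_sigmas) != 5L || any(sobel_sigmas <= 0) ||
      is.unsorted(sobel_sigmas, strictly = TRUE))
    stop_validation("`sobel_sigmas` must be 5 strictly increasing positive values")
  if (length(gabor_frequencies) != 3L || any(gabor_frequencies <= 0))
    stop_validation("`gabor_frequencies` must be 3 positive values")
  if (length(gabor_orientations) != 4L ||
      any(gabor_orientations < 0 | gabor_orientations >= pi))
    stop_validation("`gabor_orientations` must be 4 angles in [0, pi)")
  check_scalar_number(hessian_sigma, "hessian_sigma", lower = 1e-6)
  n <- length(gaussian_sigmas) + length(sobel_sigmas) +
    length(gabor_frequencies) * length(gabor_orientations) + 3L
  if (n != 25L)  # defensive; cannot trigger with the length checks above
    stop_validation("feature configuration must define exactly 25 channels")
  structure(list(gaussian_sigmas = as.numeric(gaussian_sigmas),
                 sobel_sigmas = as.numeric(sobel_sigmas),
                 gabor_frequencies = as.numeric(gabor_frequencies),
                 gabor_orientations = as.numeric(gabor_orientations),
                 hessian_sigma = as.numeric(hessian_sigma)),
            class = "feature_config")
}

feature_config_hash <- function(cfg) rlang::hash(unclass(cfg))

# quadrature-pair Gabor kernels; the even (cosine) part is zero-meaned so
# the magnitude response is invariant to the local brightness offset
gabor_kernels <- function(frequency, orientation, aspect = 0.5,
                          bandwidth_sigma = 0.56) {
  sigma <- bandwidth_sigma / frequency
  r <- max(2L, ceiling(2.5 * sigma))
  x <- matrix(-r:r, 2 * r + 1, 2 * r + 1, byrow = TRUE)  # column offset
  y <- matrix(-r:r, 2 * r + 1, 2 * r + 1)                # row offset
  xp <- x * cos(orientation) + y * sin(orientation)
  yp <- -x * sin(orientation) + y * cos(orientation)
  env <- exp(-(xp^2 + (aspect * yp)^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * frequency * xp)
  odd <- env * sin(2 * pi * frequency * xp)
  even <- even - env * sum(even) / sum(env)  # remove DC leakage
  list(even = even, odd = odd)
}

sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8  # d/dcol
sobel_y <- t(sobel_x)                                         # d/drow

#' Compute the 25-channel feature stack of a grayscale image
#'
#' Channel layout (names in `dimnames(stack)[[3]]`):
#' \itemize{
#'   \item 1-5: Gaussian blur at `gaussian_sigmas`
#'   \item 6-10: Sobel gradient magnitude of the Gaussian blur at
#'     `sobel_sigmas`
#'   \item 11-22: Gabor magnitude (quadrature pair) over the 3 x 4
#'     frequency/orientation grid, frequency-major
#'   \item 23-25: Hessian at `hessian_sigma`: larger eigenvalue, smaller
#'     eigenvalue, determinant
#' }
#'
#' @param img grayscale matrix.
#' @param cfg a [feature_config()].
#' @return `H x W x 25` numeric array of class `feature_stack` with the
#'   configuration attached as attributes `config` and `config_hash`.
#' @export
compute_feature_stack <- function(img, cfg = feature_config()) {
  img <- as_gray_matrix(img)
  if (!inherits(cfg, "feature_config"))
    stop_validation("`cfg` must come from feature_config()")
  H <- nrow(img); W <- ncol(img)
  channels <- vector("list", 25L)
  nm <- character(25L)
  k <- 0L
  for (s in cfg$gaussian_sigmas) {
    k <- k + 1L
    channels[[k]] <- gaussian_blur(img, s)
    nm[k] <- sprintf("gaussian_s%g", s)
  }
  for (s in cfg$sobel_sigmas) {
    k <- k + 1L
    sm <- gaussian_blur(img, s)
    gx <- convolve_reflect(sm, sobel_x)
    gy <- convolve_reflect(sm, sobel_y)
    channels[[k]] <- sqrt(gx^2 + gy^2)
    nm[k] <- sprintf("sobel_gaussian_s%g", s)
  }
  for (f in cfg$gabor_frequencies) {
    for (th in cfg$gabor_orientations) {
      k <- k + 1L
      kk <- gabor_kernels(f, th)
      re <- convolve_reflect(img, kk$even)
      im <- convolve_reflect(img, kk$odd)
      channels[[k]] <- sqrt(re^2 + im^2)
      nm[k] <- sprintf("gabor_f%g_o%g", f, round(th / pi * 180))
    }
  }
  sm <- gaussian_blur(img, cfg$hessian_sigma)
  d2 <- matrix(c(1, -2, 1), 1, 3)
  ixx <- convolve_reflect(sm, d2)           # second derivative along cols
  iyy <- convolve_reflect(sm, t(d2))        # along rows
  kxy <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3) / 4
  ixy <- convolve_reflect(sm, kxy)
  tr <- ixx + iyy
  disc <- sqrt(pmax((ixx - iyy)^2 + 4 * ixy^2, 0))
  channels[[k + 1L]] <- (tr + disc) / 2; nm[k + 1L] <- "hessian_eig1"
  channels[[k + 2L]] <- (tr - disc) / 2; nm[k + 2L] <- "hessian_eig2"
  channels[[k + 3L]] <- ixx * iyy - ixy^2; nm[k + 3L] <- "hessian_det"

  stack <- array(unlist(channels, use.names = FALSE), dim = c(H, W, 25L),
                 dimnames = list(NULL, NULL, nm))
  attr(stack, "config") <- cfg
  attr(stack, "config_hash") <- feature_config_hash(cfg)
  class(stack) <- c("feature_stack", class(stack))
  stack
}

#' Extract feature vectors at pixel coordinates
#'
#' @param stack a [compute_feature_stack()] result.
#' @param coordinates integer matrix (or 2-column data.frame) of 1-based
#'   `(row, col)` pixel coordinates.
#' @return `n x 25` numeric matrix, rows in input order, columns named by
#'   channel.
#' @export
sample_features <- function(stack, coordinates) {
  if (!inherits(stack, "feature_stack"))
    stop_validation("`stack` must come from compute_feature_stack()")
  coordinates <- as.matrix(coordinates)
  d <- dim(stack)
  nm <- dimnames(stack)[[3]]
  if (nrow(coordinates) == 0L)
    return(matrix(numeric(0), 0L, 25L, dimnames = list(NULL, nm)))
  if (ncol(coordinates) != 2L)
    stop_validation("`coordinates` must have two columns (row, col)")
  bad <- which(coordinates[, 1] < 1L | coordinates[, 1] > d[1] |
                 coordinates[, 2] < 1L | coordinates[, 2] > d[2])
  if (length(bad))
    stop_validation("coordinate out of bounds: (%d, %d) in a %d x %d image",
                    coordinates[bad[1], 1], coordinates[bad[1], 2],
                    d[1], d[2])
  flat <- matrix(unclass(stack), d[1] * d[2], d[3])
  out <- flat[(coordinates[, 2] - 1L) * d[1] + coordinates[, 1], ,
              drop = FALSE]
  colnames(out) <- nm
  out
}
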
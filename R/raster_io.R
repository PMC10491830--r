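# Raster input/output and grayscale conversion.
#
# The working representation is deliberately plain: an RGB image is an
# H x W x 3 integer array of 8-bit intensities, a grayscale image an H x W
# numeric matrix on the same [0, 255] scale (real values are permitted after
# filtering), and a mask an H x W 0/1 integer matrix. Geometry is row-major
# with the origin at the top-left pixel.

#' Construct an RGB image object
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 255]`.
#' @return An object of class `rgb_image`: an integer `H x W x 3` array.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_validation("an RGB image must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop_validation("image has zero-size geometry (%d x %d)", d[1], d[2])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_validation("RGB intensities must lie in [0, 255]")
  out <- array(as.integer(round(pixels)), dim = d)
  class(out) <- c("rgb_image", class(out))
  out
}

#' Construct a binary mask
#'
#' @param pixels logical or 0/1 numeric `H x W` matrix.
#' @return An object of class `binary_mask`: a 0/1 integer matrix.
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels))
    stop_validation("a mask must be an H x W matrix")
  out <- matrix(as.integer(pixels != 0), nrow = nrow(pixels))
  class(out) <- c("binary_mask", class(out))
  out
}

#' Number of foreground pixels in a mask
#'
#' @param mask a [binary_mask()] (or any 0/1 matrix).
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) sum(mask != 0)

#' Read a micrograph from disk
#'
#' Reads PNG, TIFF (including 16-bit) or JPEG and canonicalizes to 8-bit RGB.
#' 16-bit samples are mapped onto `[0, 255]` by integer division (`%/% 257`,
#' so 0 maps to 0 and 65535 to 255); single-channel images are replicated to
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a PNG, TIFF or JPEG file.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop_validation("`path` must be a single file path")
  if (!file.exists(path))
    stop_io("image file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      x <- png::readPNG(path, info = TRUE)
      depth <- attr(x, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      v <- round(unclass(x) * (2^depth - 1))
      if (depth > 8L) v <- v %/% 257L
      v
    },
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
      depth <- attr(x, "bits.per.sample")
      if (is.null(depth)) depth <- 8L
      v <- unclass(x)
      if (depth > 8L) v <- v %/% 257L
      v
    },
    jpg = ,
    jpeg = round(unclass(jpeg::readJPEG(path)) * 255),
    stop_io("unsupported image format '.%s' (expected PNG/TIFF/JPEG): %s",
            ext, path)
  )
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (length(dim(px)) != 3L)
    stop_io("could not interpret %s as a raster image", path)
  if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 1L) px <- array(rep(px, 3L), dim = c(dim(px)[1:2], 3L))
  rgb_image(px)
}

#' Write an image or mask as PNG
#'
#' PNG is the only output format (lossless, so write/read round trips are
#' bit-identical). Masks are encoded 0/255.
#'
#' @param img an [rgb_image()], grayscale matrix, or [binary_mask()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (inherits(img, "binary_mask")) {
    png::writePNG(matrix((img != 0) * 1.0, nrow = nrow(img)), path)
  } else if (is.matrix(img)) {
    png::writePNG(pmin(pmax(unclass(img), 0), 255) / 255, path)
  } else {
    png::writePNG(array(unclass(img) / 255, dim = dim(img)), path)
  }
  invisible(path)
}

#' Read a 0/255-encoded mask PNG
#'
#' @param path path to a mask PNG written by [write_image()].
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  g <- to_grayscale(read_image(path), method = "red")
  binary_mask(g > 127)
}

#' Convert an RGB image to grayscale
#'
#' The dark blue stain absorbs red light strongly, so the red channel gives
#' the best fungal contrast; BT.601 luminance is the neutral default.
#'
#' @param img an [rgb_image()].
#' @param method one of `"luminance"` (0.299 R + 0.587 G + 0.114 B, rounded
#'   half-up), `"red"`, `"green"`, `"blue"` (channel selection) or `"mean"`
#'   (arithmetic mean of the three channels).
#' @return A numeric `H x W` matrix of class `gray_image`, values in
#'   `[0, 255]`.
#' @export
to_grayscale <- function(img,
                         method = c("luminance", "red", "green", "blue",
                                    "mean")) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L))
    stop_validation("`img` must be an H x W x 3 RGB image")
  method <- match.arg(method)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  out <- switch(method,
    luminance = round_half_up(0.299 * r + 0.587 * g + 0.114 * b),
    red = r, green = g, blue = b,
    mean = (r + g + b) / 3
  )
  out <- matrix(as.numeric(out), nrow = dim(img)[1])
  class(out) <- c("gray_image", class(out))
  out
}

# internal: accept gray_image or plain numeric matrix
as_gray_matrix <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_validation("`%s` must be a numeric H x W grayscale matrix", name)
  if (anyNA(img) || any(!is.finite(img)))
    stop_validation("`%s` contains non-finite values", name)
  unclass(img)
}

check_same_geometry <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop_validation("%s have mismatched geometry: %s vs %s", what,
                    paste(dim(a)[1:2], collapse = "x"),
                    paste(dim(b)[1:2], collapse = "x"))
  invisible(TRUE)
}
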
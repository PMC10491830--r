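# Global brightness thresholding: the digital reimplementation of the
# ImageJ-style macro. The root is first isolated from the near-white
# background, then every pixel strictly darker than the chosen cutoff inside
# the root is counted as stained (colonized) area.

# 8-connected component labelling (EBImage::bwlabel is 4-connected)
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(matrix(0L, nr, nc))
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_along(fg)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    dr <- off[1]; dc <- off[2]
    r <- (fg - 1L) %% nr + 1L
    c <- (fg - 1L) %/% nr + 1L
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- idx[cbind(r2[ok], c2[ok])]
    src <- idx[fg][ok]
    keep <- nb > 0L
    edges <- c(edges, rbind(src[keep], nb[keep]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab <- matrix(0L, nr, nc)
  lab[fg] <- comp
  lab
}

#' Isolate the root section from the image background
#'
#' Pixels darker than `bg_cutoff` are candidate tissue; the candidate mask
#' is hole-filled and then cleaned by keeping every 8-connected component
#' covering at least 0.1% of the image area (dust and isolated debris are
#' dropped). An empty mask is a legal result on pure-background frames.
#'
#' @param img grayscale matrix (`[0, 255]`).
#' @param bg_cutoff background intensity cutoff in `[0, 255]`; the default
#'   240 assumes a near-white brightfield background.
#' @return A [binary_mask()] of the root section.
#' @export
extract_root_mask <- function(img, bg_cutoff = 240) {
  img <- as_gray_matrix(img)
  check_scalar_number(bg_cutoff, "bg_cutoff", 0, 255)
  cand <- img < bg_cutoff
  if (!any(cand)) return(binary_mask(cand))
  filled <- EBImage::fillHull(matrix(as.numeric(cand), nrow(cand))) > 0
  lab <- label_components8(filled)
  sizes <- tabulate(lab[lab > 0L])
  min_area <- 0.001 * length(img)
  keep <- which(sizes >= min_area)
  binary_mask(matrix(lab %in% keep, nrow(img)))
}

#' Select pixels strictly below a brightness threshold
#'
#' Implements the macro's selection rule: a pixel is selected iff its
#' brightness is strictly below `threshold` (so a uniform image at the
#' threshold value selects nothing) and it lies inside `within`.
#'
#' @param img grayscale matrix.
#' @param threshold brightness cutoff in `[0, 255]`.
#' @param within a [binary_mask()] restricting the selection (same
#'   geometry as `img`); defaults to the full frame.
#' @return A [binary_mask()].
#' @export
threshold_select <- function(img, threshold,
                             within = binary_mask(matrix(TRUE, nrow(img),
                                                         ncol(img)))) {
  img <- as_gray_matrix(img)
  check_scalar_number(threshold, "threshold", 0, 255)
  check_same_geometry(img, within, "image and mask")
  binary_mask((img < threshold) & (within != 0))
}

#' Measure an image with the thresholding engine
#'
#' Root isolation, dark-pixel selection and the t-index in one step: the
#' colonized area is the pixel count strictly below `threshold` inside the
#' extracted root mask, the reference area is the root mask area. A frame
#' with no detectable root yields a zero measure flagged `"empty"`.
#'
#' @param img grayscale matrix, or an [rgb_image()] (converted with
#'   `gray_method`).
#' @param threshold brightness cutoff; the default 100 is the operating
#'   point used for routine screening of stained roots.
#' @param bg_cutoff background cutoff for [extract_root_mask()].
#' @param gray_method grayscale conversion for RGB inputs
#'   (see [to_grayscale()]).
#' @param image_id identifier recorded in the result.
#' @return A [colonization_measure()] with `method = "threshold"`.
#' @export
measure_threshold <- function(img, threshold = 100, bg_cutoff = 240,
                              gray_method = "luminance",
                              image_id = "image") {
  if (inherits(img, "rgb_image") ||
      (is.array(img) && length(dim(img)) == 3L))
    img <- to_grayscale(img, gray_method)
  img <- as_gray_matrix(img)
  root <- extract_root_mask(img, bg_cutoff)
  total <- mask_area(root)
  colonized <- if (total > 0) mask_area(threshold_select(img, threshold, root))
  else 0L
  m <- colonization_measure(image_id, colonized, total, method = "threshold")
  m$threshold <- threshold
  m$bg_cutoff <- bg_cutoff
  m
}
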
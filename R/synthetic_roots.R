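# Synthetic stained-root micrographs with known ground truth.
#
# Scenes emulate what a 4x brightfield objective sees in a methylene/lactic
# blue stained root segment: a lighter translucent root band on a near-white
# background, with dark blue intraradical fungal structures (curvilinear
# hyphae, dense dendritic arbuscules confined to cell-sized patches, and
# ellipsoidal vesicles), optionally dark extraradical hyphae outside the
# root. Ground-truth root and colonized masks accompany every image, so both
# segmentation engines can be validated without any real micrograph.

#' Parameters of a synthetic stained-root scene
#'
#' Intensity levels are mean grayscale values in `[0, 255]` and must satisfy
#' `background_level > root_level > fungus_level` (the stain makes fungal
#' structures the darkest objects in the frame). `target_colonization` is the
#' fraction of root area to be covered by intraradical fungal structures; the
#' generator places structures until the achieved fraction is within 0.02 of
#' the target or the placement budget runs out.
#'
#' @param geometry integer `(height, width)` in pixels.
#' @param root_width_fraction fraction of image height occupied by the root
#'   band, in (0, 1).
#' @param target_colonization requested colonized fraction of root area,
#'   in `[0, 1]`.
#' @param n_arbuscules,n_hyphae,n_vesicles non-negative structure counts per
#'   placement cycle; the cycle repeats until the target fraction is reached.
#' @param include_extraradical also draw runner hyphae outside the root
#'   (never counted as colonization).
#' @param background_level,root_level,fungus_level mean intensities.
#' @param noise_sd standard deviation of additive Gaussian sensor noise.
#' @param illumination_gradient relative amplitude in `[0, 1]` of a linear
#'   left-to-right illumination ramp (0 disables it).
#' @param placement_budget maximum number of structure placement attempts.
#' @param seed integer RNG seed; scenes are bit-reproducible given the seed.
#' @return An object of class `scene_params` (a validated list).
#' @export
scene_params <- function(geometry = c(180L, 240L),
                         root_width_fraction = 0.55,
                         target_colonization = 0.30,
                         n_arbuscules = 6L,
                         n_hyphae = 10L,
                         n_vesicles = 4L,
                         include_extraradical = FALSE,
                         background_level = 250,
                         root_level = 230,
                         fungus_level = 80,
                         noise_sd = 0,
                         illumination_gradient = 0,
                         placement_budget = 1200L,
                         seed = 1L) {
  if (length(geometry) != 2L || any(geometry < 8))
    stop_validation("`geometry` must be (height, width), each >= 8")
  check_scalar_number(root_width_fraction, "root_width_fraction", 0.05, 0.95)
  check_scalar_number(target_colonization, "target_colonization", 0, 1)
  for (nm in c("n_arbuscules", "n_hyphae", "n_vesicles")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != floor(v))
      stop_validation("`%s` must be a non-negative integer", nm)
  }
  check_scalar_number(background_level, "background_level", 0, 255)
  check_scalar_number(root_level, "root_level", 0, 255)
  check_scalar_number(fungus_level, "fungus_level", 0, 255)
  if (!(background_level > root_level && root_level > fungus_level))
    stop_validation(
      "intensity ordering background_level > root_level > fungus_level required")
  check_scalar_number(noise_sd, "noise_sd", 0, Inf)
  check_scalar_number(illumination_gradient, "illumination_gradient", 0, 1)
  check_scalar_number(placement_budget, "placement_budget", 1, Inf)
  check_scalar_number(seed, "seed", -2^31, 2^31 - 1)
  structure(list(
    geometry = as.integer(geometry),
    root_width_fraction = root_width_fraction,
    target_colonization = target_colonization,
    n_arbuscules = as.integer(n_arbuscules),
    n_hyphae = as.integer(n_hyphae),
    n_vesicles = as.integer(n_vesicles),
    include_extraradical = isTRUE(include_extraradical),
    background_level = background_level,
    root_level = root_level,
    fungus_level = fungus_level,
    noise_sd = noise_sd,
    illumination_gradient = illumination_gradient,
    placement_budget = as.integer(placement_budget),
    seed = as.integer(seed)
  ), class = "scene_params")
}

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# -- structure stencils ------------------------------------------------------

# mark all pixels within `radius` of the given (row, col) points
stamp_points <- function(mask, pts, radius) {
  if (nrow(pts) == 0L) return(mask)
  r <- ceiling(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
  rr <- rep(pts[, 1], each = nrow(off)) + off$dr
  cc <- rep(pts[, 2], each = nrow(off)) + off$dc
  keep <- rr >= 1L & rr <= nrow(mask) & cc >= 1L & cc <= ncol(mask)
  mask[cbind(rr[keep], cc[keep])] <- TRUE
  mask
}

# smoothed random walk -> curvilinear stroke, ~3 px wide
draw_hypha <- function(dim2, center, length_range = c(40L, 110L)) {
  m <- matrix(FALSE, dim2[1], dim2[2])
  n <- sample(length_range[1]:length_range[2], 1L)
  theta <- runif(1, 0, 2 * pi)
  pos <- center
  pts <- matrix(0L, n, 2L)
  for (i in seq_len(n)) {
    theta <- theta + rnorm(1, 0, 0.25)
    pos <- pos + c(sin(theta), cos(theta))
    pts[i, ] <- round(pos)
  }
  stamp_points(m, pts, radius = 1.2)
}

# dense dendritic blob confined to an elliptical cell-sized patch
draw_arbuscule <- function(dim2, center) {
  a <- runif(1, 7, 13); b <- runif(1, 5, 10); phi <- runif(1, 0, pi)
  m <- matrix(FALSE, dim2[1], dim2[2])
  n_branch <- sample(8:14, 1L)
  for (k in seq_len(n_branch)) {
    theta <- runif(1, 0, 2 * pi)
    steps <- ceiling(max(a, b))
    pos <- center
    pts <- matrix(0L, steps, 2L)
    for (i in seq_len(steps)) {
      theta <- theta + rnorm(1, 0, 0.35)
      pos <- pos + c(sin(theta), cos(theta))
      pts[i, ] <- round(pos)
    }
    m <- stamp_points(m, pts, radius = 1.3)
  }
  # clip to the elliptical patch
  rows <- row(m) - center[1]; cols <- col(m) - center[2]
  xr <- cols * cos(phi) + rows * sin(phi)
  yr <- -cols * sin(phi) + rows * cos(phi)
  m & (xr^2 / a^2 + yr^2 / b^2 <= 1)
}

# filled ellipse (lipid storage vesicle)
draw_vesicle <- function(dim2, center) {
  a <- runif(1, 4, 8); b <- runif(1, 3, 6); phi <- runif(1, 0, pi)
  rows <- matrix(seq_len(dim2[1]), dim2[1], dim2[2]) - center[1]
  cols <- matrix(seq_len(dim2[2]), dim2[1], dim2[2], byrow = TRUE) - center[2]
  xr <- cols * cos(phi) + rows * sin(phi)
  yr <- -cols * sin(phi) + rows * cos(phi)
  xr^2 / a^2 + yr^2 / b^2 <= 1
}

# -- scene assembly ----------------------------------------------------------

render_root_mask <- function(H, W, width_fraction) {
  x <- seq_len(W)
  centre <- H / 2 + 0.04 * H * sin(2 * pi * x / W * runif(1, 0.7, 1.4) +
                                     runif(1, 0, 2 * pi))
  half <- (width_fraction * H / 2) *
    (1 + 0.08 * sin(2 * pi * x / W * runif(1, 1, 2) + runif(1, 0, 2 * pi)))
  rows <- matrix(seq_len(H), H, W)
  abs(rows - matrix(centre, H, W, byrow = TRUE)) <=
    matrix(half, H, W, byrow = TRUE)
}

# map a mean grayscale level to a bluish RGB triple with that luminance
stain_rgb <- function(level, tint) {
  r <- max(0, level - tint)
  b <- min(255, level + tint)
  g <- (level - 0.299 * r - 0.114 * b) / 0.587
  c(r, min(max(g, 0), 255), b)
}

#' Generate one synthetic stained-root scene
#'
#' Deterministic for a given seed. Structures are placed one at a time, each
#' centred on a not-yet-colonized root pixel, cycling through the configured
#' mix of hyphae, arbuscules and vesicles, until the colonized fraction of
#' the root is within 0.02 of `target_colonization` or the placement budget
#' is exhausted (the achieved fraction is then reported in the result and
#' flagged). Noise and the illumination ramp are applied last, so the
#' noise-free scene has strict intensity separation between fungus, root
#' tissue and background.
#'
#' @param params a [scene_params()].
#' @return An object of class `synthetic_scene`: list with `image`
#'   ([rgb_image()]), `root_mask`, `colonized_mask` ([binary_mask()]),
#'   `true_fraction`, `params` and `flags`.
#' @export
generate_scene <- function(params) {
  if (!inherits(params, "scene_params"))
    stop_validation("`params` must come from scene_params()")
  with_seed(params$seed, {
    H <- params$geometry[1]; W <- params$geometry[2]
    root <- render_root_mask(H, W, params$root_width_fraction)
    root_area <- sum(root)
    colonized <- matrix(FALSE, H, W)
    extraradical <- matrix(FALSE, H, W)
    flags <- character(0)

    weights <- c(arbuscule = params$n_arbuscules,
                 hypha = params$n_hyphae,
                 vesicle = params$n_vesicles)
    target <- params$target_colonization
    tol <- 0.02
    if (target > tol && sum(weights) == 0L)
      stop(errorCondition(
        sprintf(paste0("placement failure: no structure types enabled, ",
                       "achieved fraction 0 for target %.3f"), target),
        class = c("rootquant_placement_error", "error")))

    frac <- 0
    if (sum(weights) > 0L) {
      pool <- sample(rep(names(weights), weights))
      pool_i <- 0L
      attempts <- 0L
      while (frac < target - tol && attempts < params$placement_budget) {
        attempts <- attempts + 1L
        pool_i <- pool_i + 1L
        if (pool_i > length(pool)) {
          pool <- sample(rep(names(weights), weights))
          pool_i <- 1L
        }
        open <- which(root & !colonized)
        if (length(open) == 0L) break
        idx <- open[sample.int(length(open), 1L)]
        center <- c((idx - 1L) %% H + 1L, (idx - 1L) %/% H + 1L)
        st <- switch(pool[pool_i],
                     arbuscule = draw_arbuscule(c(H, W), center),
                     hypha = draw_hypha(c(H, W), center),
                     vesicle = draw_vesicle(c(H, W), center))
        st <- st & root   # intraradical only
        cand <- colonized | st
        cand_frac <- sum(cand) / root_area
        if (cand_frac <= target + tol) {
          colonized <- cand
          frac <- cand_frac
        }
      }
      if (frac < target - tol)
        flags <- c(flags, "placement_budget_exhausted")
    }

    if (params$include_extraradical) {
      for (k in seq_len(sample(1:3, 1L))) {
        open_bg <- which(!root)
        idx <- open_bg[sample.int(length(open_bg), 1L)]
        center <- c((idx - 1L) %% H + 1L, (idx - 1L) %/% H + 1L)
        st <- draw_hypha(c(H, W), center, length_range = c(60L, 140L))
        extraradical <- extraradical | (st & !root)
      }
    }

    # compose intensities; fungal pixels darkest, background lightest
    bg_rgb <- stain_rgb(params$background_level, 2)
    root_rgb <- stain_rgb(params$root_level, 12)
    fun_rgb <- stain_rgb(params$fungus_level, 30)
    fungal <- colonized | extraradical
    img <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) {
      plane <- matrix(bg_rgb[ch], H, W)
      plane[root] <- root_rgb[ch]
      plane[fungal] <- fun_rgb[ch]
      plane <- gaussian_blur(plane, 0.7)   # soften edges (anti-aliased look)
      if (params$illumination_gradient > 0) {
        ramp <- 1 + params$illumination_gradient *
          ((seq_len(W) - 1) / (W - 1) - 0.5)
        plane <- plane * matrix(ramp, H, W, byrow = TRUE)
      }
      if (params$noise_sd > 0)
        plane <- plane + matrix(rnorm(H * W, 0, params$noise_sd), H, W)
      img[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }

    structure(list(
      image = rgb_image(img),
      root_mask = binary_mask(root),
      colonized_mask = binary_mask(colonized),
      true_fraction = sum(colonized) / root_area,
      params = params,
      flags = flags
    ), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic_scene %dx%d | root area %d px | colonized fraction %.3f%s\n",
    x$params$geometry[1], x$params$geometry[2], mask_area(x$root_mask),
    x$true_fraction,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Canonical six-class colonization target ranges
#'
#' Colonized-fraction sampling ranges mirroring the six visual scoring
#' classes (none / traces / <10% / 11-50% / 51-90% / >90%); the top class is
#' capped at 0.95 because near-total coverage of the root band is not
#' physically meaningful for discrete fungal structures.
#'
#' @return data.frame with columns `class`, `lo`, `hi`.
#' @export
trouvelot_target_ranges <- function() {
  data.frame(class = 1:6,
             lo = c(0, 0.002, 0.01, 0.11, 0.51, 0.90),
             hi = c(0, 0.010, 0.10, 0.50, 0.90, 0.95))
}

#' Generate a multi-class synthetic dataset with manifest
#'
#' @param class_targets data.frame with columns `class`, `n`, `lo`, `hi`
#'   (target-colonization range per class); see [trouvelot_target_ranges()].
#' @param base a [scene_params()] supplying everything except the target
#'   fraction and per-scene seed (seeds are derived from `base$seed`).
#' @param dir if non-`NULL`, scenes are written there as PNGs
#'   (`<stem>.png`, `<stem>_root.png`, `<stem>_colonized.png`) along with
#'   `manifest.csv`.
#' @param keep_scenes return the scene objects (memory-hungry for large
#'   datasets; defaults to `TRUE` only when `dir` is `NULL`).
#' @return list with `manifest` (data.frame: file, class, true_fraction,
#'   seed) and `scenes` (list or `NULL`).
#' @export
generate_dataset <- function(class_targets, base = scene_params(),
                             dir = NULL, keep_scenes = is.null(dir)) {
  if (!is.data.frame(class_targets) ||
      !all(c("class", "n", "lo", "hi") %in% names(class_targets)))
    stop_validation(
      "`class_targets` must be a data.frame with columns class, n, lo, hi")
  if (nrow(class_targets) == 0L)
    stop_validation("`class_targets` must contain at least one class")
  if (any(class_targets$lo < 0 | class_targets$hi > 1 |
          class_targets$lo > class_targets$hi))
    stop_validation("target ranges must satisfy 0 <= lo <= hi <= 1")
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list(); scenes <- list(); k <- 0L
  with_seed(base$seed, {
    for (i in seq_len(nrow(class_targets))) {
      n <- class_targets$n[i]
      if (n == 0) next
      targets <- runif(n, class_targets$lo[i], class_targets$hi[i])
      for (j in seq_len(n)) {
        k <- k + 1L
        p <- base
        p$target_colonization <- targets[j]
        p$seed <- (base$seed + 7919L * k) %% .Machine$integer.max
        sc <- generate_scene(p)
        stem <- sprintf("scene_c%d_%03d", class_targets$class[i], k)
        if (!is.null(dir)) {
          write_image(sc$image, file.path(dir, paste0(stem, ".png")))
          write_image(sc$root_mask, file.path(dir, paste0(stem, "_root.png")))
          write_image(sc$colonized_mask,
                      file.path(dir, paste0(stem, "_colonized.png")))
        }
        rows[[k]] <- data.frame(file = paste0(stem, ".png"),
                                class = class_targets$class[i],
                                true_fraction = sc$true_fraction,
                                seed = p$seed)
        if (keep_scenes) scenes[[k]] <- sc
      }
    }
  })
  manifest <- if (k > 0L) do.call(rbind, rows)
  else data.frame(file = character(0), class = integer(0),
                  true_fraction = numeric(0), seed = integer(0))
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, scenes = if (keep_scenes) scenes else NULL)
}
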
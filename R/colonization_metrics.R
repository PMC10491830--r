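# Colonization indices and Trouvelot class assignment.

#' Thresholding colonization index (t-index)
#'
#' `t = 100 * mycorrhized_area / total_area`: the percentage of the root
#' section area selected as stained (dark) by the brightness threshold.
#' An empty root (`total_area = 0`) yields 0 by convention; callers that
#' need to distinguish this use [colonization_measure()], which flags it.
#'
#' @param mycorrhized_area,total_area pixel counts,
#'   `0 <= mycorrhized_area <= total_area`.
#' @return Percentage in `[0, 100]`.
#' @export
t_index <- function(mycorrhized_area, total_area) {
  if (any(mycorrhized_area < 0) || any(total_area < 0))
    stop_validation("areas must be non-negative")
  if (any(mycorrhized_area > total_area))
    stop_validation("mycorrhized_area exceeds total_area")
  ifelse(total_area > 0, 100 * mycorrhized_area / total_area, 0)
}

#' Machine-learning colonization index (ml-index)
#'
#' `ml = 100 * colonized / (colonized + non_colonized)`: the percentage of
#' classified root-tissue area labelled as colonized by the pixel
#' classifier. Both areas zero yields 0 by convention.
#'
#' @param colonized_area,non_colonized_area non-negative pixel counts.
#' @return Percentage in `[0, 100]`.
#' @export
ml_index <- function(colonized_area, non_colonized_area) {
  if (any(colonized_area < 0) || any(non_colonized_area < 0))
    stop_validation("areas must be non-negative")
  denom <- colonized_area + non_colonized_area
  ifelse(denom > 0, 100 * colonized_area / denom, 0)
}

#' Trouvelot six-class colonization score
#'
#' Maps a per-image colonization percentage onto the six visual scoring
#' classes (1 = no colonization, 2 = few traces, 3 = under 10%, 4 = 10-50%,
#' 5 = 50-90%, 6 = over 90%). The published class edges are integer
#' shorthand for a continuum; they are implemented as half-open intervals
#' with boundaries at 10, 50 and 90 so that every percentage maps to exactly
#' one class. "Few traces" has no numeric definition in the visual protocol;
#' `trace_cutoff` (default 1%) sets the class 2 / class 3 boundary.
#'
#' @param percentage colonization percentage(s) in `[0, 100]`.
#' @param trace_cutoff upper bound (exclusive of class 3) for "few traces".
#' @return Integer class(es) in 1..6.
#' @export
trouvelot_class <- function(percentage, trace_cutoff = 1) {
  if (any(!is.finite(percentage)) || any(percentage < 0 | percentage > 100))
    stop_validation("`percentage` must lie in [0, 100]")
  check_scalar_number(trace_cutoff, "trace_cutoff", 0, 10)
  cls <- rep(1L, length(percentage))
  cls[percentage > 0] <- 2L
  cls[percentage > trace_cutoff] <- 3L
  cls[percentage > 10] <- 4L
  cls[percentage > 50] <- 5L
  cls[percentage > 90] <- 6L
  cls
}

#' Colonization measurement record for one image
#'
#' @param image_id image identifier (file name or label).
#' @param colonized_area colonized pixel count.
#' @param reference_area reference pixel count (total root area for the
#'   t-index; colonized + non-colonized area for the ml-index).
#' @param method `"threshold"` or `"ml"`.
#' @param trace_cutoff passed to [trouvelot_class()].
#' @param flags character vector of processing flags.
#' @return Object of class `colonization_measure` with fields `image_id`,
#'   `colonized_area`, `reference_area`, `index_value`, `method`,
#'   `trouvelot_class`, `flags`.
#' @export
colonization_measure <- function(image_id, colonized_area, reference_area,
                                 method = c("threshold", "ml"),
                                 trace_cutoff = 1, flags = character(0)) {
  method <- match.arg(method)
  if (colonized_area < 0 || reference_area < 0)
    stop_validation("areas must be non-negative")
  if (colonized_area > reference_area)
    stop_validation("colonized_area exceeds reference_area")
  empty <- reference_area == 0
  value <- if (empty) 0 else 100 * colonized_area / reference_area
  if (empty) flags <- union(flags, "empty")
  structure(list(
    image_id = as.character(image_id),
    colonized_area = colonized_area,
    reference_area = reference_area,
    index_value = value,
    method = method,
    trouvelot_class = trouvelot_class(value, trace_cutoff),
    flags = flags
  ), class = "colonization_measure")
}

#' @export
print.colonization_measure <- function(x, ...) {
  cat(sprintf("%s [%s]: index %.2f%% (%d / %d px), class %d%s\n",
              x$image_id, x$method, x$index_value, x$colonized_area,
              x$reference_area, x$trouvelot_class,
              if (length(x$flags))
                paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.colonization_measure <- function(x, ...) {
  data.frame(file = x$image_id, method = x$method,
             colonized_area = x$colonized_area,
             reference_area = x$reference_area,
             index = x$index_value, class = x$trouvelot_class,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
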
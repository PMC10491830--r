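# Published per-class summaries bundled with the package.

#' Published per-class index summaries (180-image benchmark)
#'
#' Per-visual-class summary statistics (n, mean, sample SD, range) of the
#' t-index and ml-index from a published 180-image benchmark of stained
#' tomato-relative roots, 30 images per Trouvelot class. These summaries
#' are the inputs for the summary-based re-analysis: reconstructing the
#' one-way ANOVA tables, the Bonferroni pairwise layer and the grand means
#' without access to the raw per-image values.
#'
#' @param index `"t"` (brightness thresholding) or `"ml"` (pixel
#'   classifier).
#' @return A [group_summary()] data.frame with 6 rows (classes 1-6).
#' @export
reference_class_summaries <- function(index = c("t", "ml")) {
  index <- match.arg(index)
  path <- system.file("extdata", "reference_class_summaries.csv",
                      package = "rootquant", mustWork = TRUE)
  all <- read.csv(path, stringsAsFactors = FALSE)
  d <- all[all$index == index, ]
  group_summary(group = d$class, n = d$n, mean = d$mean, sd = d$sd,
                range = d$range)
}
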
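# Evaluation statistics: per-class descriptives, one-way ANOVA (from raw
# values or from published group summaries), Bonferroni pairwise post hoc
# comparisons, polynomial regression with R-squared, Pearson correlation,
# and the side-by-side model-comparison report.

#' Per-group descriptive statistics
#'
#' @param values numeric vector of index values.
#' @param groups grouping vector (class labels), same length.
#' @return data.frame with one row per group plus an overall row pooling
#'   all values: columns `group`, `n`, `mean`, `sd` (sample SD, n-1
#'   denominator), `range` (max - min).
#' @export
descriptives <- function(values, groups) {
  if (length(values) != length(groups))
    stop_validation("`values` and `groups` must have equal length")
  if (anyNA(values)) stop_validation("`values` contains NA")
  gl <- split(values, groups)
  if (any(lengths(gl) == 0L)) stop_validation("empty group")
  per <- data.frame(
    group = names(gl),
    n = lengths(gl),
    mean = vapply(gl, mean, 0),
    sd = vapply(gl, sd, 0),
    range = vapply(gl, function(v) diff(range(v)), 0),
    row.names = NULL
  )
  rbind(per, data.frame(group = "total", n = length(values),
                        mean = mean(values), sd = sd(values),
                        range = diff(range(values))))
}

#' Group summary rows for summary-based analyses
#'
#' @param group group identifiers.
#' @param n per-group sample sizes (each >= 2).
#' @param mean,sd per-group means and sample standard deviations.
#' @param range optional per-group ranges (max - min).
#' @return data.frame of class `group_summary`.
#' @export
group_summary <- function(group, n, mean, sd, range = NA_real_) {
  if (any(n < 2)) stop_validation("each group needs n >= 2")
  if (any(sd < 0)) stop_validation("standard deviations must be >= 0")
  out <- data.frame(group = group, n = as.integer(n), mean = mean, sd = sd,
                    range = range)
  class(out) <- c("group_summary", class(out))
  out
}

new_anova_table <- function(ssb, ssw, dfb, dfw) {
  dfb <- as.integer(round(dfb)); dfw <- as.integer(round(dfw))
  msb <- ssb / dfb
  msw <- ssw / dfw
  f <- if (msw > 0) msb / msw else Inf
  p <- if (is.finite(f)) pf(f, dfb, dfw, lower.tail = FALSE) else 0
  structure(list(ss_between = ssb, ss_within = ssw, ss_total = ssb + ssw,
                 df_between = dfb, df_within = dfw, df_total = dfb + dfw,
                 ms_between = msb, ms_within = msw, F = f, p = p,
                 flags = if (is.finite(f)) character(0) else
                   "zero_within_variance"),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  tab <- data.frame(
    source = c("between groups", "within groups", "total"),
    ss = c(x$ss_between, x$ss_within, x$ss_total),
    df = c(x$df_between, x$df_within, x$df_total),
    ms = c(x$ms_between, x$ms_within, NA),
    F = c(x$F, NA, NA),
    p = c(x$p, NA, NA))
  print(tab, row.names = FALSE, digits = 6)
  invisible(x)
}

#' One-way ANOVA from raw per-group values
#'
#' Classical fixed-effects decomposition (equal-variance, as in standard
#' statistical packages), fitted via [stats::aov()]. If every value is
#' identical the within-group mean square is zero and `F` is reported as
#' `Inf` with a `zero_within_variance` flag rather than failing.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return An `anova_table`: sums of squares, degrees of freedom, mean
#'   squares, `F` and the upper-tail p-value.
#' @export
anova_raw <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_validation("need >= 2 groups")
  if (any(lengths(groups) < 2L))
    stop_validation("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  sm <- summary(aov(y ~ g))[[1]]
  new_anova_table(ssb = sm["g", "Sum Sq"],
                  ssw = sm["Residuals", "Sum Sq"],
                  dfb = sm["g", "Df"],
                  dfw = sm["Residuals", "Df"])
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Rebuilds the full ANOVA table from per-group `(n, mean, sd)` alone:
#' within-group SS is `sum((n_i - 1) sd_i^2)`, the grand mean is the
#' n-weighted mean of means, and between-group SS is
#' `sum(n_i (mean_i - grand)^2)`. Given summaries computed from raw data
#' this reproduces [anova_raw()] exactly, which is how published summary
#' tables are re-analysed without the raw per-image values.
#'
#' @param summaries a [group_summary()] data.frame (or any data.frame with
#'   columns `n`, `mean`, `sd`).
#' @return An `anova_table`.
#' @export
anova_from_summaries <- function(summaries) {
  if (!is.data.frame(summaries) ||
      !all(c("n", "mean", "sd") %in% names(summaries)))
    stop_validation("`summaries` needs columns n, mean, sd")
  if (nrow(summaries) < 2L) stop_validation("need >= 2 groups")
  if (any(summaries$n < 2)) stop_validation("each group needs n >= 2")
  n <- summaries$n; m <- summaries$mean; s <- summaries$sd
  grand <- sum(n * m) / sum(n)
  new_anova_table(ssb = sum(n * (m - grand)^2),
                  ssw = sum((n - 1) * s^2),
                  dfb = nrow(summaries) - 1L,
                  dfw = sum(n) - nrow(summaries))
}

#' Bonferroni pairwise post hoc comparisons
#'
#' For every pair of groups, the difference of means is tested with a
#' pooled-variance t statistic, `t = diff / sqrt(MSw (1/n_i + 1/n_j))` on
#' the within-group degrees of freedom, and the two-sided p-value is
#' multiplied by the number of comparisons (capped at 1). If the
#' within-group mean square is zero, every nonzero difference is flagged
#' significant with p = 0.
#'
#' @param x either a list of raw value vectors or a [group_summary()]
#'   data.frame.
#' @param alpha family-wise significance level.
#' @return data.frame of class `pairwise_table` with one row per unordered
#'   pair: `group_i`, `group_j`, `mean_diff` (mean_j - mean_i), `t`,
#'   `p_adjusted`, `significant`; attribute `method = "bonferroni"`.
#' @export
bonferroni_pairwise <- function(x, alpha = 0.05) {
  check_scalar_number(alpha, "alpha", 0, 1)
  if (is.data.frame(x)) {
    summaries <- x
    an <- anova_from_summaries(summaries)
  } else {
    summaries <- group_summary(
      group = if (!is.null(names(x))) names(x) else seq_along(x),
      n = lengths(x),
      mean = vapply(x, mean, 0),
      sd = vapply(x, sd, 0))
    an <- anova_raw(x)
  }
  k <- nrow(summaries)
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  rows <- lapply(seq_len(n_comp), function(pi) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    diff <- summaries$mean[j] - summaries$mean[i]
    if (an$ms_within > 0) {
      se <- sqrt(an$ms_within * (1 / summaries$n[i] + 1 / summaries$n[j]))
      tstat <- diff / se
      p <- min(1, 2 * pt(-abs(tstat), an$df_within) * n_comp)
      sig <- p < alpha
    } else {
      tstat <- if (diff == 0) 0 else sign(diff) * Inf
      p <- if (diff == 0) 1 else 0
      sig <- diff != 0
    }
    data.frame(group_i = summaries$group[i], group_j = summaries$group[j],
               mean_diff = diff, t = tstat, p_adjusted = p,
               significant = sig)
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- "bonferroni"
  attr(out, "df_within") <- an$df_within
  attr(out, "ms_within") <- an$ms_within
  class(out) <- c("pairwise_table", class(out))
  out
}

#' Polynomial regression of visual score on an index
#'
#' Ordinary least squares of `y` on powers of `x` up to `degree`
#' (`y = a + b1 x + ... + bd x^d`), with `R^2 = 1 - SSres/SStot` about the
#' mean of `y`. By convention `R^2 = 0` when `y` is constant (`SStot = 0`).
#' In the method-evaluation workflow `x` is the per-image colonization
#' index and `y` the visual class score.
#'
#' @param x,y numeric vectors of equal length.
#' @param degree polynomial degree, 1 (linear), 2 (quadratic) or 3 (cubic).
#' @return Object of class `polynomial_fit`: `degree`, `coefficients`
#'   (length degree + 1, intercept first) and `r_squared`.
#' @export
fit_polynomial <- function(x, y, degree = 3L) {
  if (!degree %in% 1:3) stop_validation("`degree` must be 1, 2 or 3")
  if (length(x) != length(y))
    stop_validation("`x` and `y` must have equal length")
  if (length(x) <= degree + 1L)
    stop_validation("need more than degree + 1 = %d points", degree + 1L)
  if (length(unique(x)) == 1L)
    stop_validation("all x values are equal; design is rank-deficient")
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  res <- y - fitted(fit)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum(res^2) / sstot else 0
  cf <- unname(coef(fit))
  structure(list(degree = as.integer(degree),
                 coefficients = setNames(cf, c("a", paste0("b",
                                                           seq_len(degree)))),
                 r_squared = r2),
            class = "polynomial_fit")
}

#' @export
print.polynomial_fit <- function(x, ...) {
  cat(sprintf("polynomial fit (degree %d): R^2 = %.4f\n", x$degree,
              x$r_squared))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return Sample Pearson r in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_validation("`x` and `y` must have equal length >= 3")
  if (var(x) == 0 || var(y) == 0)
    stop_validation("Pearson correlation undefined for constant input")
  stats::cor(x, y, method = "pearson")
}

#' Side-by-side model-performance report
#'
#' Collates, for the thresholding and machine-learning methods, the linear
#' / quadratic / cubic R-squared of the index-vs-visual-score fits and the
#' count of significant Bonferroni pairwise comparisons.
#'
#' @param t_fits,ml_fits lists of three [fit_polynomial()] results (degrees
#'   1, 2, 3) for each method.
#' @param t_pairwise,ml_pairwise [bonferroni_pairwise()] tables.
#' @return data.frame with 4 rows (`R2 linear`, `R2 quadratic`, `R2 cubic`,
#'   `significant`) and one column per method.
#' @export
model_report <- function(t_fits, ml_fits, t_pairwise, ml_pairwise) {
  get_r2 <- function(fits) {
    if (length(fits) != 3L)
      stop_validation("expected fits of degrees 1, 2, 3")
    deg <- vapply(fits, function(f) f$degree, 0L)
    vapply(fits[order(deg)], function(f) f$r_squared, 0)
  }
  sig <- function(pw) sprintf("%d/%d", sum(pw$significant), nrow(pw))
  data.frame(
    performance = c("R2 linear", "R2 quadratic", "R2 cubic", "significant"),
    thresholding = c(format(get_r2(t_fits), digits = 3), sig(t_pairwise)),
    machine_learning = c(format(get_r2(ml_fits), digits = 3),
                         sig(ml_pairwise)),
    stringsAsFactors = FALSE)
}
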
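test_that("descriptives report n, mean, sample SD and range per group", {
  d <- descriptives(c(5, 5, 5, 1, 3), c("a", "a", "a", "b", "b"))
  a <- d[d$group == "a", ]; b <- d[d$group == "b", ]
  expect_equal(c(a$mean, a$sd, a$range), c(5, 0, 0))
  expect_equal(c(b$mean, b$sd, b$range), c(2, sqrt(2), 2))
  tot <- d[d$group == "total", ]
  expect_equal(tot$n, 5L)
  expect_error(descriptives(1:3, c("a", "a")),
               class = "rootquant_validation_error")
})

test_that("raw one-way ANOVA matches the hand decomposition", {
  an <- anova_raw(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(an$ss_between, 13.5)
  expect_equal(an$ss_within, 4)
  expect_equal(an$df_between, 1L)
  expect_equal(an$df_within, 4L)
  expect_equal(an$F, 13.5)
  expect_equal(an$ss_total, an$ss_between + an$ss_within)

  same <- anova_raw(list(c(1, 2, 3), c(2, 1, 3)))
  expect_equal(same$ss_between, 0)
  expect_equal(same$F, 0)

  const <- anova_raw(list(c(2, 2), c(2, 2)))
  expect_true(is.infinite(const$F))
  expect_true("zero_within_variance" %in% const$flags)
})

test_that("summary-based ANOVA reproduces the raw decomposition exactly", {
  set.seed(21)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    groups <- lapply(seq_len(k), function(i)
      rnorm(sample(5:40, 1), mean = runif(1, 0, 50), sd = runif(1, 1, 15)))
    s <- group_summary(group = seq_len(k), n = lengths(groups),
                       mean = vapply(groups, mean, 0),
                       sd = vapply(groups, sd, 0))
    a_raw <- anova_raw(groups)
    a_sum <- anova_from_summaries(s)
    for (f in c("ss_between", "ss_within", "ms_between", "ms_within", "F"))
      expect_equal(a_sum[[f]], a_raw[[f]], tolerance = 1e-9)
    expect_identical(a_sum$df_within, a_raw$df_within)
  }
  expect_error(anova_from_summaries(group_summary(1:2, c(2, 2), c(1, 2),
                                                  c(0, 0))[1, ]),
               class = "rootquant_validation_error")
})

test_that("Bonferroni pairwise matches a brute-force pooled-t oracle", {
  set.seed(33)
  groups <- lapply(1:4, function(i) rnorm(12, mean = 2 * i, sd = 3))
  pw <- bonferroni_pairwise(groups, alpha = 0.05)
  expect_equal(nrow(pw), choose(4, 2))

  # independent oracle: pooled MS across all groups, p * n_pairs
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) /
    (sum(lengths(groups)) - 4)
  dfw <- sum(lengths(groups)) - 4
  for (r in seq_len(nrow(pw))) {
    i <- as.integer(pw$group_i[r]); j <- as.integer(pw$group_j[r])
    diff <- mean(groups[[j]]) - mean(groups[[i]])
    tstat <- diff / sqrt(msw * (1 / 12 + 1 / 12))
    p <- min(1, 2 * pt(-abs(tstat), dfw) * choose(4, 2))
    expect_equal(pw$mean_diff[r], diff)
    expect_equal(pw$p_adjusted[r], p, tolerance = 1e-12)
    expect_identical(pw$significant[r], p < 0.05)
  }
})

test_that("pairwise comparisons on identical groups find nothing", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  pw <- bonferroni_pairwise(g)
  expect_equal(sum(pw$significant), 0L)
  expect_true(all(pw$mean_diff == 0))
})

test_that("the mean-difference structure is antisymmetric under relabeling", {
  set.seed(9)
  groups <- lapply(1:4, function(i) rnorm(10, i, 2))
  pw1 <- bonferroni_pairwise(groups)
  pw2 <- bonferroni_pairwise(rev(groups))
  expect_equal(sum(pw1$significant), sum(pw2$significant))
  # pair (i, j) in reversed ordering carries the negated difference
  d1 <- pw1$mean_diff[pw1$group_i == 1 & pw1$group_j == 4]
  d2 <- pw2$mean_diff[pw2$group_i == 1 & pw2$group_j == 4]
  expect_equal(d1, -d2)
})

test_that("polynomial fits match the closed-form normal equations", {
  set.seed(17)
  x <- runif(40, 0, 10)
  y <- 2 - 0.5 * x + 0.3 * x^2 - 0.01 * x^3 + rnorm(40, 0, 0.5)
  for (d in 1:3) {
    fit <- fit_polynomial(x, y, d)
    X <- outer(x, 0:d, `^`)
    beta <- solve(t(X) %*% X, t(X) %*% y)[, 1]
    expect_equal(unname(fit$coefficients), unname(beta), tolerance = 1e-8)
    expect_equal(length(fit$coefficients), d + 1L)
  }
  # exact cubic -> R^2 = 1; constant y -> R^2 = 0 by convention
  y3 <- 1 + x - 2 * x^2 + 0.1 * x^3
  expect_equal(fit_polynomial(x, y3, 3)$r_squared, 1)
  expect_equal(fit_polynomial(x, rep(2, 40), 2)$r_squared, 0)
  expect_error(fit_polynomial(rep(1, 10), rnorm(10), 2),
               class = "rootquant_validation_error")
})

test_that("R^2 is non-decreasing in polynomial degree (nested models)", {
  set.seed(29)
  for (rep in 1:5) {
    x <- rnorm(30); y <- rnorm(30, sin(x))
    r2 <- vapply(1:3, function(d) fit_polynomial(x, y, d)$r_squared, 0)
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("pearson matches the covariance formula and validates input", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  set.seed(41)
  x <- rnorm(50); y <- rnorm(50)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), hand, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), class = "rootquant_validation_error")
})

test_that("the comparison report has four rows and mirrors identical input", {
  set.seed(53)
  x <- runif(60, 0, 40)
  y <- trouvelot_class(pmin(x * 2.2, 100))
  fits <- lapply(1:3, function(d) fit_polynomial(x, y, d))
  pw <- bonferroni_pairwise(split(x, y))
  rep_tab <- model_report(fits, fits, pw, pw)
  expect_equal(nrow(rep_tab), 4L)
  expect_identical(rep_tab$thresholding, rep_tab$machine_learning)
})
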
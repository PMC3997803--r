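pw_truth <- function(x, psi = 20, y0 = 0.83, b1 = 0.048, b2 = 0.0056) {
  y0 + b1 * pmin(x - psi, 0) + b2 * pmax(x - psi, 0)
}

test_that("piecewise regression recovers a noiseless two-segment model", {
  x <- 9:62
  fit <- fit_piecewise(x, pw_truth(x))
  expect_equal(fit$breakpoint, 20, tolerance = 1e-6)
  expect_equal(fit$y_at_break, 0.83, tolerance = 1e-6)
  expect_equal(fit$left_slope, 0.048, tolerance = 1e-6)
  expect_equal(fit$right_slope, 0.0056, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(predict(fit, c(10, 20, 40)), pw_truth(c(10, 20, 40)),
               tolerance = 1e-6)
})

test_that("piecewise regression degrades gracefully", {
  x <- 1:20
  suppressWarnings(fit <- fit_piecewise(x, rep(0.5, 20)))
  expect_equal(fit$left_slope, 0, tolerance = 1e-9)
  expect_equal(fit$right_slope, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 0)
  expect_error(fit_piecewise(1:6, rnorm(6)), "at least 7")
  expect_error(fit_piecewise(rep(1:3, 5), rnorm(15)), "distinct")
  # kink beyond the admissible range: boundary fit with a warning
  expect_warning(fit_piecewise(1:30, c(rep(0, 29), 5)), "boundary")
})

test_that("piecewise fit never loses to the nested straight line", {
  set.seed(31)
  for (i in 1:15) {
    x <- runif(40, 0, 50)
    y <- 0.5 + 0.01 * x + rnorm(40, 0, 0.1)
    pw <- suppressWarnings(fit_piecewise(x, y))
    ln <- fit_linear(x, y)
    rss_lin <- sum(stats::resid(ln$lm)^2)
    expect_lte(pw$rss, rss_lin + 1e-10)
  }
})

test_that("break-point estimate is affine-equivariant in the predictor", {
  set.seed(17)
  x <- runif(60, 5, 60)
  y <- pw_truth(x) + rnorm(60, 0, 0.05)
  f1 <- fit_piecewise(x, y)
  f2 <- fit_piecewise(2.5 * x + 7, y)
  expect_equal(f2$breakpoint, 2.5 * f1$breakpoint + 7, tolerance = 1e-5)
  expect_equal(f2$y_at_break, f1$y_at_break, tolerance = 1e-7)
})

test_that("saturating fit recovers noiseless hyperbola coefficients", {
  x <- seq(0.5, 7, by = 0.25)
  y <- 1.03 * x / (0.92 + x)
  fit <- fit_saturating(x, y)
  expect_equal(fit$a, 1.03, tolerance = 1e-6)
  expect_equal(fit$k, 0.92, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("saturating prediction and inversion follow the hyperbola", {
  m <- saturating_model(a = 1.03, k = 0.92)
  expect_equal(predict_saturating(m, 0), 0)
  expect_equal(predict_saturating(m, 0.92), 1.03 / 2)
  expect_equal(round(predict_saturating(m, 3.818), 3), 0.830)
  expect_equal(predict_saturating(m, 1e9), 1.03, tolerance = 1e-6)
  expect_equal(solve_saturating_inverse(m, 1.03 / 2), 0.92)
  expect_equal(solve_saturating_inverse(saturating_model(1, 1), 0.5), 1)
  expect_error(predict_saturating(m, -1), "domain")
  expect_error(solve_saturating_inverse(m, 1.2), "unreachable")
})

test_that("regression tree splits step data at the midpoint", {
  x <- 5:30
  y <- as.numeric(x >= 15)
  fit <- fit_regression_tree(x, y, seed = 1)
  # exhaustive single-split search oracle over midpoints
  xs <- sort(unique(x))
  cand <- (head(xs, -1) + tail(xs, -1)) / 2
  sse <- vapply(cand, function(s) {
    sum((y[x < s] - mean(y[x < s]))^2) + sum((y[x >= s] - mean(y[x >= s]))^2)
  }, numeric(1))
  expect_equal(fit$splits, cand[which.min(sse)])
  expect_equal(fit$splits, 14.5)
  expect_equal(fit$chosen_size, 2L)
  expect_equal(sort(fit$node_means), c(0, 1))
  expect_equal(fit$r2_equivalent, 1, tolerance = 1e-9)
})

test_that("regression tree degenerates to the root where it should", {
  expect_equal(fit_regression_tree(1:20, rep(0.4, 20))$chosen_size, 1L)
  expect_equal(fit_regression_tree(1:20, rep(0.4, 20))$r2_equivalent, 0)
  expect_warning(out <- fit_regression_tree(1:12, rnorm(12), min_leaf = 7),
                 "root-only")
  expect_equal(out$chosen_size, 1L)
})

test_that("tree and piecewise break agree on noiseless kinked data", {
  # a genuine slope change (not a level step): both detectors localize it
  x <- seq(2, 40, by = 0.5)
  y <- pw_truth(x, psi = 21.5, y0 = 0.6, b1 = 0.03, b2 = 0)
  pw <- fit_piecewise(x, y)
  expect_equal(pw$breakpoint, 21.5, tolerance = 1e-5)
  tree <- fit_regression_tree(x, y, seed = 3)
  expect_gte(length(tree$splits), 1L)
  # the tree approximates the ramp below the kink with steps, all of
  # which sit at or below the break
  expect_lte(max(tree$splits), 21.5 + 0.5)
})

test_that("linear fit reports exact coefficients and honest nulls", {
  x <- seq(1, 10, by = 0.5)
  f <- suppressWarnings(fit_linear(x, 2 * x + 1))
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_linear(rep(3, 10), rnorm(10)), "degenerate")
  # under a zero-slope truth the test rejects at its nominal rate
  set.seed(23)
  p <- replicate(400, fit_linear(1:20, rnorm(20))$p_value)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("litter-slope and break-point recovery on default synthetic data", {
  ds <- generate_dataset(fast_config(), seed = 1, tracer = FALSE)
  tr <- ds$truth
  pw <- fit_piecewise(tr$R_CN, tr$NUE_true)
  expect_lte(abs(pw$breakpoint - 20), 4.6)
  litter <- tr$substrate == "litter"
  lin <- fit_linear(tr$R_CN[litter], tr$NUE_true[litter])
  # litter lies above the threshold: NUE still rises, but much more
  # slowly than below it
  expect_gt(lin$slope, 0)
  expect_lt(lin$slope, pw$left_slope / 3)
  # the attainable truth is the slope of the *clipped* mean function
  # (NUE saturates at 1 on the most N-poor litter), computed from a
  # zero-noise run at the same seed
  cfg0 <- fast_config()
  cfg0$nue$sd <- 0
  tr0 <- generate_dataset(cfg0, seed = 1, tracer = FALSE)$truth
  lin0 <- fit_linear(tr0$R_CN[litter], tr0$NUE_true[litter])
  expect_lte(abs(lin$slope - lin0$slope), 2.5 * lin$slope_se)
})

test_that("tree root split on default synthetic data sits in the break region", {
  tr <- generate_dataset(fast_config(), seed = 1, tracer = FALSE)$truth
  x <- tr$R_CN; y <- tr$NUE_true
  tree <- fit_regression_tree(x, y, seed = 1)
  expect_gte(length(tree$splits), 1L)
  root_split <- unname(tree$rpart$splits[1, "index"])
  # exhaustive single-split oracle
  xs <- sort(unique(x))
  cand <- (head(xs, -1) + tail(xs, -1)) / 2
  sse <- vapply(cand, function(s) {
    sum((y[x < s] - mean(y[x < s]))^2) + sum((y[x >= s] - mean(y[x >= s]))^2)
  }, numeric(1))
  expect_equal(root_split, cand[which.min(sse)], tolerance = 1e-9)
  expect_gte(root_split, 12)
  expect_lte(root_split, 25)
})
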
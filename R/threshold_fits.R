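#' @title Threshold and curve models for NUE
#' @description Models of NUE against resource C:N or C:N imbalance used
#'   to locate the switch from C to N limitation: a continuous two-segment
#'   (break-point) regression, a single-predictor regression tree pruned
#'   by the 1-SE rule, a saturating rectangular hyperbola
#'   `y = a x / (k + x)`, and ordinary linear regression.
#' @name threshold_fits
NULL

# residual sum of squares of the two-segment model at a fixed break psi
.pw_rss <- function(psi, x, y) {
  X <- cbind(1, pmin(x, psi), pmax(x - psi, 0))
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

# golden-section minimisation, deterministic, ties toward the smaller psi
.golden <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a)
  d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (b - a > tol) {
    if (fc <= fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(d_)
    }
  }
  if (fc <= fd) c_ else d_
}

#' Continuous two-segment (break-point) regression
#'
#' Fits `y = a + b1 x` for `x <= psi` joined continuously to
#' `y = a + b1 psi + b2 (x - psi)` for `x > psi` by least squares.  The
#' break point `psi` is found by profiling the residual sum of squares
#' over a dense grid (201 points by default) between the break-point
#' bounds, followed by golden-section refinement; ties are broken toward
#' the smaller `psi`.  The grid is restricted so that at least
#' `min_per_side` observations lie on each side of the break.  The
#' break-point standard error comes from the Jacobian-based large-sample
#' covariance of the four-parameter nonlinear least-squares problem.
#'
#' @param x predictor (e.g. resource C:N), needs >= 5 distinct values.
#' @param y response (e.g. NUE); `length(y) == length(x)`, n >= 7.
#' @param n_grid number of profile grid points (default 201).
#' @param min_per_side minimum observations required on each side of the
#'   break (default 3).
#' @return object of class `piecewise_fit` with `breakpoint`,
#'   `breakpoint_se`, `left_slope`, `right_slope`, `left_intercept`,
#'   `y_at_break`, `r_squared`, `f_statistic`, `df` (3, n-4), `p_value`,
#'   `rss`, `n`, and the data for the methods.  If the RSS profile has no
#'   interior minimum a boundary fit is returned with a warning.
#' @export
fit_piecewise <- function(x, y, n_grid = 201L, min_per_side = 3L) {
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 7L) stop("need at least 7 observations", call. = FALSE)
  if (length(unique(x)) < 5L) {
    stop("need at least 5 distinct predictor values", call. = FALSE)
  }
  xs <- sort(x)
  eps <- 1e-8 * (xs[n] - xs[1L])
  # between the 2nd and (n-1)th order statistics, tightened to keep
  # min_per_side observations on each side
  lo <- max(xs[2L], xs[min_per_side])
  hi <- min(xs[n - 1L], xs[n + 1L - min_per_side] - eps)
  if (hi <= lo) stop("predictor too degenerate for a break point",
                     call. = FALSE)
  grid <- seq(lo, hi, length.out = n_grid)
  rss_grid <- vapply(grid, .pw_rss, numeric(1L), x = x, y = y)
  i <- which.min(rss_grid)  # first minimum -> smaller psi on ties
  boundary <- i == 1L || i == n_grid
  if (boundary) {
    warning("no interior RSS minimum: break point at the search boundary",
            call. = FALSE)
  }
  a_ <- grid[max(1L, i - 1L)]
  b_ <- grid[min(n_grid, i + 1L)]
  psi <- .golden(function(p) .pw_rss(p, x, y), a_, b_,
                 tol = 1e-9 * (hi - lo))
  if (.pw_rss(grid[i], x, y) < .pw_rss(psi, x, y)) psi <- grid[i]

  X <- cbind(1, pmin(x, psi), pmax(x - psi, 0))
  ls <- stats::lm.fit(X, y)
  beta <- ls$coefficients
  rss <- sum(ls$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  dfree <- c(3L, n - 4L)
  fstat <- if (rss > 0) ((tss - rss) / dfree[1L]) / (rss / dfree[2L]) else Inf
  pval <- if (is.finite(fstat)) {
    stats::pf(fstat, dfree[1L], dfree[2L], lower.tail = FALSE)
  } else 0
  # asymptotic covariance treating psi as a regular fourth parameter
  J <- cbind(X, (beta[2L] - beta[3L]) * as.numeric(x > psi))
  sigma2 <- rss / dfree[2L]
  se_psi <- tryCatch(sqrt(sigma2 * solve(crossprod(J))[4L, 4L]),
                     error = function(e) NA_real_)
  structure(list(breakpoint = psi,
                 breakpoint_se = se_psi,
                 left_intercept = unname(beta[1L]),
                 left_slope = unname(beta[2L]),
                 right_slope = unname(beta[3L]),
                 y_at_break = unname(beta[1L] + beta[2L] * psi),
                 r_squared = r2, f_statistic = fstat, df = dfree,
                 p_value = pval, rss = rss, n = n,
                 boundary = boundary, x = x, y = y),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("Two-segment (break-point) regression\n")
  cat(sprintf("  break point: %.4g (se %.3g), y at break: %.4g\n",
              x$breakpoint, x$breakpoint_se, x$y_at_break))
  cat(sprintf("  slopes: %.4g (below) / %.4g (above); R^2 %.3f, F(%d,%d) = %.4g, P %.3g, n %d\n",
              x$left_slope, x$right_slope, x$r_squared, x$df[1L], x$df[2L],
              x$f_statistic, x$p_value, x$n))
  invisible(x)
}

#' @export
coef.piecewise_fit <- function(object, ...) {
  c(left_intercept = object$left_intercept, left_slope = object$left_slope,
    right_slope = object$right_slope, breakpoint = object$breakpoint)
}

#' @export
predict.piecewise_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  object$left_intercept + object$left_slope * pmin(x, object$breakpoint) +
    object$right_slope * pmax(x - object$breakpoint, 0)
}

#' @export
residuals.piecewise_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
plot.piecewise_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "predictor", ylab = "response", ...)
  xx <- seq(min(x$x), max(x$x), length.out = 200L)
  graphics::lines(xx, predict(x, xx), col = "red3", lwd = 2)
  graphics::abline(v = x$breakpoint, lty = 2, col = "grey40")
  invisible(x)
}

#' Saturating model constructor
#'
#' Builds a `saturating_fit` object from known coefficients of the
#' rectangular hyperbola `y = a x / (k + x)` without fitting, for
#' prediction and inversion with published coefficients.
#'
#' @param a asymptote (response units), > 0.
#' @param k half-saturation constant (predictor units), > 0.
#' @return object of class `saturating_fit`.
#' @export
saturating_model <- function(a, k) {
  stopifnot(a > 0, k > 0)
  structure(list(a = a, k = k, a_se = NA_real_, k_se = NA_real_,
                 r_squared = NA_real_, f_statistic = NA_real_,
                 df = c(NA_integer_, NA_integer_), p_value = NA_real_,
                 n = NA_integer_),
            class = "saturating_fit")
}

#' Saturating (rectangular hyperbola) regression
#'
#' Least-squares fit of `y = a x / (k + x)` by Levenberg-Marquardt
#' (damped Gauss-Newton) iteration with multi-start initialization: the
#' asymptote is started at and above the response maximum, the
#' half-saturation constant at several quantiles of the predictor.  The
#' converged start with the lowest residual sum of squares wins;
#' the result does not depend on start order beyond this deterministic
#' rule.
#'
#' @param x predictor (e.g. C:N imbalance), all > 0, n >= 4.
#' @param y response (e.g. NUE).
#' @return object of class `saturating_fit` with `a`, `k`, their standard
#'   errors, `r_squared`, `f_statistic` with `df` (1, n-2), `p_value`,
#'   `n`.
#' @export
fit_saturating <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (any(x <= 0)) stop("all predictor values must be > 0", call. = FALSE)
  dat <- data.frame(x = x, y = y)
  a_starts <- max(y) * c(1, 1.25, 2)
  k_starts <- unname(stats::quantile(x, c(0.1, 0.25, 0.5, 0.75)))
  best <- NULL
  for (a0 in a_starts) {
    for (k0 in k_starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * x / (k + x), data = dat,
                          start = list(a = a0, k = k0),
                          lower = c(a = 1e-10, k = 1e-10),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss - 1e-12 * max(1, best$rss)) {
          best <- list(fit = fit, rss = rss)
        }
      }
    }
  }
  if (is.null(best)) {
    stop("convergence error: saturating fit failed from all starts",
         call. = FALSE)
  }
  fit <- best$fit
  cf <- stats::coef(fit)
  sm <- summary(fit)
  rss <- best$rss
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  dfree <- c(1L, n - 2L)
  fstat <- if (rss > 0) ((tss - rss) / dfree[1L]) / (rss / dfree[2L]) else Inf
  pval <- if (is.finite(fstat)) {
    stats::pf(fstat, dfree[1L], dfree[2L], lower.tail = FALSE)
  } else 0
  structure(list(a = unname(cf["a"]), k = unname(cf["k"]),
                 a_se = sm$coefficients["a", 2L],
                 k_se = sm$coefficients["k", 2L],
                 r_squared = r2, f_statistic = fstat, df = dfree,
                 p_value = pval, n = n, x = x, y = y),
            class = "saturating_fit")
}

#' @export
print.saturating_fit <- function(x, ...) {
  cat("Saturating regression: y = a x / (k + x)\n")
  cat(sprintf("  a (asymptote) = %.4g (se %.3g), k (half-saturation) = %.4g (se %.3g)\n",
              x$a, x$a_se, x$k, x$k_se))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R^2 %.3f, F(%d,%d) = %.4g, P %.3g, n %d\n", x$r_squared,
                x$df[1L], x$df[2L], x$f_statistic, x$p_value, x$n))
  }
  invisible(x)
}

#' @export
coef.saturating_fit <- function(object, ...) {
  c(a = object$a, k = object$k)
}

#' Evaluate a saturating fit
#'
#' `y = a x / (k + x)`.
#'
#' @param fit a `saturating_fit` (fitted or from [saturating_model()]).
#' @param x predictor values, >= 0.
#' @return predicted response; 0 at `x = 0`, `a/2` at `x = k`, approaching
#'   `a` as `x` grows.
#' @export
predict_saturating <- function(fit, x) {
  stopifnot(inherits(fit, "saturating_fit"))
  if (any(x < 0)) stop("domain error: x must be >= 0", call. = FALSE)
  fit$a * x / (fit$k + x)
}

#' @export
predict.saturating_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  predict_saturating(object, x)
}

#' Invert a saturating fit
#'
#' Solves `y = a x / (k + x)` for the predictor: `x = y k / (a - y)`.
#' Used to read off, e.g., the C:N imbalance at which NUE reaches a given
#' level.
#'
#' @param fit a `saturating_fit`.
#' @param y response value with `0 < y < a`.
#' @return the predictor value at which the fitted curve attains `y`.
#' @export
solve_saturating_inverse <- function(fit, y) {
  stopifnot(inherits(fit, "saturating_fit"))
  if (any(y <= 0) || any(y >= fit$a)) {
    stop("unreachable value: need 0 < y < a (asymptote ", signif(fit$a, 4),
         ")", call. = FALSE)
  }
  y * fit$k / (fit$a - y)
}

#' Single-predictor regression tree with 1-SE pruning
#'
#' Binary recursive partitioning of the response on one predictor
#' (`rpart`, ANOVA method, splits at midpoints of consecutive distinct
#' predictor values), followed by cost-complexity pruning: k-fold
#' cross-validation (fold assignment seeded for reproducibility) selects
#' the smallest tree whose cross-validated relative error is within one
#' standard error of the minimum.
#'
#' Relative errors follow the usual CART conventions: resubstitution
#' relative error = SSE(tree)/SSE(root); cv relative error =
#' cross-validated SSE/SSE(root).
#'
#' @param x predictor; @param y response; n >= 10.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param min_leaf minimum observations per leaf (default 7).
#' @return object of class `tree_fit`: `splits` (ordered thresholds, empty
#'   for a root-only tree), `node_means` (response mean per leaf, in leaf
#'   order), `cv_error`, `r2_equivalent` (= 1 - resubstitution relative
#'   error), `chosen_size` (leaf count) and the pruned `rpart` object.
#' @export
fit_regression_tree <- function(x, y, cv_folds = 10L, seed = 1L,
                                min_leaf = 7L) {
  keep <- !is.na(x) & !is.na(y)
  dat <- data.frame(x = as.numeric(x[keep]), y = as.numeric(y[keep]))
  n <- nrow(dat)
  if (n < 10L) stop("need at least 10 observations", call. = FALSE)
  if (n < 2L * min_leaf || stats::var(dat$y) == 0) {
    if (n < 2L * min_leaf) {
      warning("too few observations for a split: returning root-only tree",
              call. = FALSE)
    }
    return(structure(list(splits = numeric(0L), node_means = mean(dat$y),
                          cv_error = NA_real_, r2_equivalent = 0,
                          chosen_size = 1L, rpart = NULL, n = n),
                     class = "tree_fit"))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  tree <- rpart::rpart(y ~ x, data = dat, method = "anova",
                       control = rpart::rpart.control(
                         minsplit = 2L * min_leaf, minbucket = min_leaf,
                         cp = 1e-4, xval = cv_folds, maxcompete = 0L,
                         maxsurrogate = 0L))
  cp <- tree$cptable
  if (is.null(cp) || nrow(cp) == 1L) {
    chosen_row <- 1L
    pruned <- tree
  } else {
    i_min <- which.min(cp[, "xerror"])
    thr <- cp[i_min, "xerror"] + cp[i_min, "xstd"]
    chosen_row <- which(cp[, "xerror"] <= thr)[1L]  # smallest tree in range
    pruned <- rpart::prune(tree, cp = cp[chosen_row, "CP"])
  }
  is_leaf <- pruned$frame$var == "<leaf>"
  splits <- if (any(!is_leaf)) {
    sort(unname(pruned$splits[, "index"]))
  } else numeric(0L)
  structure(list(splits = splits,
                 node_means = pruned$frame$yval[is_leaf],
                 cv_error = unname(cp[chosen_row, "xerror"]),
                 r2_equivalent = 1 - unname(cp[chosen_row, "rel error"]),
                 chosen_size = sum(is_leaf), rpart = pruned, n = n),
            class = "tree_fit")
}

#' @export
print.tree_fit <- function(x, ...) {
  cat(sprintf("Regression tree (1-SE pruned): %d leaf/leaves\n",
              x$chosen_size))
  if (length(x$splits)) {
    cat("  splits at:", paste(signif(x$splits, 5), collapse = ", "), "\n")
  }
  cat(sprintf("  leaf means: %s\n",
              paste(signif(x$node_means, 4), collapse = ", ")))
  cat(sprintf("  cv relative error %.3f, R^2 equivalent %.3f, n %d\n",
              x$cv_error, x$r2_equivalent, x$n))
  invisible(x)
}

#' Ordinary least-squares line
#'
#' Simple linear regression with the standard ANOVA F test and two-sided
#' p-value.
#'
#' @param x predictor with non-zero variance, n >= 3.
#' @param y response.
#' @return object of class `linear_fit`: `slope`, `intercept`, `slope_se`,
#'   `r_squared`, `f_statistic`, `df` (1, n-2), `p_value`, `n` and the
#'   underlying `lm`.
#' @export
fit_linear <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate: predictor has zero variance",
                               call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- if (is.null(sm$fstatistic)) Inf else unname(sm$fstatistic[1L])
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_se = sm$coefficients[2L, 2L],
                 r_squared = sm$r.squared,
                 f_statistic = fstat,
                 df = c(1L, n - 2L),
                 p_value = sm$coefficients[2L, 4L],
                 n = n, lm = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "Linear fit: y = %.4g + %.4g x; R^2 %.3f, F(%d,%d) = %.4g, P %.3g, n %d\n",
    x$intercept, x$slope, x$r_squared, x$df[1L], x$df[2L], x$f_statistic,
    x$p_value, x$n))
  invisible(x)
}

#' @export
coef.linear_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.linear_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$lm$model$x
       else if (is.list(newdata)) newdata$x else newdata
  object$intercept + object$slope * x
}
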
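#' @title Nonparametric comparison of NUE between substrate types
#' @description Kruskal-Wallis rank test (tie-corrected) with Dunn's
#'   pairwise post-hoc Q statistics, the standard procedure when the
#'   assumptions of a parametric one-way analysis are not met.
#' @name group_stats
NULL

.as_group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (any(vapply(groups, length, integer(1L)) < 2L)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `g - 1` degrees of freedom (delegates to [stats::kruskal.test()]).
#' When every observation is identical H is 0 and p is 1.
#'
#' @param groups a named list of numeric vectors (one per group, each of
#'   length >= 2).
#' @return list of class `kw_test`: `H`, `df`, `p_value`, `n_per_group`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- .as_group_list(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(values)) == 1L) {
    out <- list(H = 0, df = length(groups) - 1L, p_value = 1,
                n_per_group = lengths(groups))
  } else {
    kt <- stats::kruskal.test(values, g)
    out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value, n_per_group = lengths(groups))
  }
  structure(out, class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.4g, P = %.3g  (n = %s)\n",
              x$df, x$H, x$p_value,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' For each pair of groups the Q statistic compares mean ranks in the
#' pooled mid-rank ordering,
#' `Q = |Rbar_i - Rbar_j| / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`,
#' where `T = sum(t^3 - t) / (12 (N - 1))` corrects for ties.
#' Significance at family-wise level `alpha` uses the Bonferroni-adjusted
#' two-sided normal critical value for `g(g-1)/2` comparisons; exact
#' Bonferroni-adjusted p-values are reported alongside.
#'
#' @inheritParams kruskal_wallis
#' @param alpha family-wise error rate for the significance flags
#'   (default 0.05).
#' @return data frame of class `dunn_test` with columns `group_i`,
#'   `group_j`, `Q`, `p_adjusted`, `significant`.
#' @export
dunn_test <- function(groups, alpha = 0.05) {
  groups <- .as_group_list(groups)
  values <- unlist(groups, use.names = FALSE)
  idx <- rep(seq_along(groups), lengths(groups))
  N <- length(values)
  r <- rank(values)  # mid-ranks
  rbar <- tapply(r, idx, mean)
  nn <- lengths(groups)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var_core <- N * (N + 1) / 12 - tie_term
  g <- length(groups)
  m <- g * (g - 1L) / 2L
  crit <- stats::qnorm(1 - alpha / (2 * m))
  pairs <- utils::combn(g, 2L)
  Q <- p_adj <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    se <- sqrt(var_core * (1 / nn[i1] + 1 / nn[i2]))
    Q[j] <- if (se > 0) abs(rbar[i1] - rbar[i2]) / se else 0
    p_adj[j] <- min(1, 2 * m * stats::pnorm(-Q[j]))
  }
  out <- data.frame(group_i = names(groups)[pairs[1L, ]],
                    group_j = names(groups)[pairs[2L, ]],
                    Q = Q, p_adjusted = p_adj,
                    significant = Q > crit,
                    stringsAsFactors = FALSE)
  class(out) <- c("dunn_test", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Kruskal-Wallis test plus Dunn post-hoc in one call
#'
#' @inheritParams dunn_test
#' @return list of class `group_comparison` with elements `kruskal`
#'   ([kruskal_wallis()] result) and `pairwise` ([dunn_test()] result).
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  structure(list(kruskal = kruskal_wallis(groups),
                 pairwise = dunn_test(groups, alpha = alpha)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$kruskal)
  print(as.data.frame(x$pairwise))
  invisible(x)
}
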
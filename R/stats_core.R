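#' Correlation with pairwise-complete deletion
#'
#' Pearson or Spearman correlation of two numeric vectors. Missing entries
#' are removed pairwise and the number of pairs actually used is reported.
#' Spearman is computed as the product-moment correlation of midranks; the
#' two-sided p-value uses the t approximation with `n - 2` degrees of
#' freedom for both methods.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return an object of class `correlation_result`: a list with `estimate`,
#'   `p_value`, `n`, and `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop_insufficient(sprintf("only %d complete pairs (need >= 3)", n))
  if (length(unique(x)) < 2) stop_degenerate("x is constant after pairwise deletion")
  if (length(unique(y)) < 2) stop_degenerate("y is constant after pairwise deletion")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  est <- stats::cor(x, y)
  correlation_result(est, n, method, df = n - 2L)
}

# Shared p-value machinery: t approximation, two-sided.
correlation_result <- function(estimate, n, method, df) {
  estimate <- max(-1, min(1, estimate))
  if (df < 1 || is.na(estimate)) {
    stop_degenerate("correlation undefined (insufficient degrees of freedom)")
  }
  if (abs(estimate) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- estimate * sqrt(df / (1 - estimate^2))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  structure(
    list(estimate = estimate, p_value = p, n = as.integer(n), method = method),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<%s> estimate = %.4f, p = %.3g, n = %d\n",
              x$method, x$estimate, x$p_value, x$n))
  invisible(x)
}

#' Partial correlation controlling for one covariate
#'
#' Residual definition: `x` and `y` are each regressed on `control` (with
#' intercept) and the residuals are correlated. For the Spearman variant all
#' three vectors are midrank-transformed first, then the residual definition
#' is applied to the ranks. The p-value uses `n - 3` degrees of freedom (one
#' lost to the control).
#'
#' @param x,y,control numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return a `correlation_result` with method `partial_pearson` or
#'   `partial_spearman`.
#' @export
partial_correlate <- function(x, y, control, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) != length(control)) {
    stop_validation("x, y, control must have equal length")
  }
  ok <- stats::complete.cases(x, y, control)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok]); z <- as.numeric(control[ok])
  n <- length(x)
  if (n < 4) stop_insufficient(sprintf("only %d complete triples (need >= 4)", n))
  if (length(unique(x)) < 2) stop_degenerate("x is constant")
  if (length(unique(y)) < 2) stop_degenerate("y is constant")
  if (length(unique(z)) < 2) stop_degenerate("control is constant")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  tol <- 1e-12 * max(1, stats::sd(x))
  if (stats::sd(rx) <= tol) stop_degenerate("x is collinear with control")
  if (stats::sd(ry) <= tol) stop_degenerate("y is collinear with control")
  est <- stats::cor(rx, ry)
  correlation_result(est, n, paste0("partial_", method), df = n - 3L)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with enforced monotonicity. NA entries are excluded from the
#' family and returned as NA; `m` is the number of non-missing p-values.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_validation("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0) return(q)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  qv <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  q[ok] <- qv
  q
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided test using midranks, the normal approximation with
#' tie-corrected variance, and a 0.5 continuity correction. The statistic
#' reported is U for group `a`: the count of pairs with `a_i > b_j` plus
#' half the tied pairs, so U = 0 means `a` lies entirely below `b`.
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @return list with `statistic` (U for `a`), `p_value`, `n_a`, `n_b`, and a
#'   `method` record noting the approximation used.
#' @export
rank_sum_test <- function(a, b) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) {
    stop_insufficient("each group needs >= 2 non-missing observations")
  }
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  mu <- n1 * n2 / 2
  if (v <= 0) {
    p <- 1
  } else {
    z <- (u_a - mu)
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
  }
  list(
    statistic = u_a, p_value = p, n_a = n1, n_b = n2,
    method = list(
      test = "mann-whitney", approximation = "normal",
      continuity_correction = TRUE, tie_corrected_variance = TRUE
    )
  )
}

#' Z-score standardization
#'
#' `(v - mean) / sd` with the sample (n-1) standard deviation; NAs are
#' preserved in place.
#'
#' @param v numeric vector with at least two distinct non-missing values.
#' @return numeric vector of the same length.
#' @export
zscore <- function(v) {
  v <- as.numeric(v)
  obs <- v[!is.na(v)]
  if (length(unique(obs)) < 2) stop_degenerate("cannot z-score a constant vector")
  (v - mean(obs)) / stats::sd(obs)
}
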
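#' Welch's unequal-variance t-test
#'
#' Own implementation of the two-sample t-test without the equal-variance
#' assumption: \eqn{t = (\bar x - \bar y)/\sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch–Satterthwaite degrees of freedom. Sample variances use the n-1
#' denominator. The t tail probability is evaluated with [stats::pt()] (the
#' regularized incomplete beta function).
#'
#' If both samples have zero variance: equal means give `t = 0, p = 1`;
#' unequal means give an infinite statistic and `p = 0`.
#'
#' @param x,y Numeric samples, each of length >= 2 (`NA`s dropped).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A `welch_test` object: list with `statistic`, `df`, `p.value`,
#'   `estimate` (the two means), `n` (the two sizes), `alternative`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
welch_t_test <- function(x, y,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) abort("welch_t_test needs >= 2 observations per group")
  mx <- sum(x) / nx; my <- sum(y) / ny
  vx <- sum((x - mx)^2) / (nx - 1); vy <- sum((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    t <- if (mx == my) 0 else sign(mx - my) * Inf
    df <- nx + ny - 2
  } else {
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  p <- switch(alternative,
    two.sided = if (is.infinite(t)) 0 else 2 * pt(-abs(t), df),
    less      = pt(t, df),
    greater   = pt(t, df, lower.tail = FALSE)
  )
  structure(
    list(statistic = t, df = df, p.value = min(p, 1),
         estimate = c(mean_x = mx, mean_y = my), n = c(nx = nx, ny = ny),
         alternative = alternative, method = "Welch two-sample t-test"),
    class = "welch_test"
  )
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("%s: t = %.4g, df = %.4g, p = %.4g (%s)\n",
              x$method, x$statistic, x$df, x$p.value, x$alternative))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Welch test result
#' @param x A `welch_test`.
#' @param ... Unused.
#' @return One-row tibble with estimates, statistic, df and p-value.
#' @method tidy welch_test
#' @export
tidy.welch_test <- function(x, ...) {
  tibble(
    estimate = x$estimate[[1]] - x$estimate[[2]],
    estimate1 = x$estimate[[1]], estimate2 = x$estimate[[2]],
    statistic = x$statistic, parameter = x$df, p.value = x$p.value,
    method = x$method, alternative = x$alternative
  )
}

#' Pearson correlation coefficient
#'
#' Own implementation of \eqn{r = \mathrm{cov}(x, y)/(\sigma_x \sigma_y)},
#' clamped to `[-1, 1]` against floating-point overshoot.
#'
#' @param x,y Numeric vectors of equal length >= 3; pairs with `NA` dropped.
#' @return Scalar correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("pearson_r needs >= 3 complete pairs")
  mx <- sum(x) / n; my <- sum(y) / n
  dx <- x - mx; dy <- y - my
  sx2 <- sum(dx^2); sy2 <- sum(dy^2)
  if (sx2 == 0 || sy2 == 0) abort("pearson_r undefined for zero-variance input")
  max(-1, min(1, sum(dx * dy) / sqrt(sx2 * sy2)))
}
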
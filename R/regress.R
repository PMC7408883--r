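# Off-target <-> coverage association: ordinary least squares with Pearson r
# and a two-sided p-value from the t statistic on n-2 degrees of freedom.

#' Linear association between off-target fraction and mtDNA coverage
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()]; the correlation
#' and its two-sided p-value come from the t statistic
#' `r * sqrt((n-2) / (1-r^2))` with `n - 2` degrees of freedom.
#'
#' @param x predictor (e.g. per-sample off-target mitochondrial fraction).
#' @param y response (e.g. per-sample median mtDNA coverage).
#' @return list of class `offtarget_regression`: slope, intercept, r, p, n.
#' @export
offtarget_coverage_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = r, p = p, n = n),
    class = "offtarget_regression"
  )
}

#' @export
print.offtarget_regression <- function(x, ...) {
  cat(sprintf(
    "<offtarget_regression> n=%d: y = %.4g + %.4g x, r = %.2f, p = %.2g\n",
    x$n, x$intercept, x$slope, x$r, x$p))
  invisible(x)
}
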
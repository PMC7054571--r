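# The small statistical toolkit used to validate automated against manual
# volumes and to relate them to behaviour: Pearson correlation, partial
# correlation, comparison of two dependent correlations sharing a common
# variable, and the paired t test. Routine distributions come from stats;
# the dependent-correlation comparison is implemented here.

#' Pearson correlation with a two-tailed p value
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @return List with `r` and `p_two_tailed` (t distributed with n - 2 df).
#' @export
cor_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_two_tailed = ct$p.value)
}

#' Partial correlation controlling for covariates
#'
#' Correlates the least-squares residuals of `x` and `y` after projecting
#' each onto the covariates (plus an intercept). With no covariates this
#' reduces to the plain Pearson correlation. The p value is one-tailed for
#' the positive direction (the alternative that the partial correlation
#' exceeds zero), from a t distribution with `n - 2 - k` degrees of
#' freedom, `k` the number of covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (n x k) or `NULL`.
#' @return List with `r`, `df` and `p_one_tailed`.
#' @export
cor_partial <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- 0L
  if (!is.null(covariates) && length(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have n rows")
    k <- ncol(covariates)
    if (qr(cbind(1, covariates))$rank < k + 1L)
      stop("covariate matrix is rank deficient")
    sx <- stats::sd(x); sy <- stats::sd(y)
    x <- stats::lm.fit(cbind(1, covariates), x)$residuals
    y <- stats::lm.fit(cbind(1, covariates), y)$residuals
    if (stats::sd(x) <= 1e-10 * max(sx, 1) ||
        stats::sd(y) <= 1e-10 * max(sy, 1))
      stop("zero residual variance: partial correlation undefined")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero residual variance: partial correlation undefined")
  r <- stats::cor(x, y)
  df <- n - 2L - k
  if (df < 1L) stop("not enough observations for ", k, " covariates")
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p_one_tailed = stats::pt(t, df, lower.tail = FALSE))
}

#' Compare two dependent correlations sharing a common variable
#'
#' Tests whether `r1 = cor(reference, method1)` exceeds `r2 =
#' cor(reference, method2)` when both are computed on the same sample and
#' share the reference variable, given `r12 = cor(method1, method2)`. Uses
#' the Meng-Rosenthal-Rubin z statistic on Fisher-transformed
#' correlations:
#' \deqn{z = (atanh(r1) - atanh(r2)) \sqrt{(n - 3) / (2 (1 - r12) h)}}
#' with \eqn{\bar r^2 = (r1^2 + r2^2)/2},
#' \eqn{f = \min(1, (1 - r12) / (2 (1 - \bar r^2)))} and
#' \eqn{h = (1 - f \bar r^2) / (1 - \bar r^2)}. The one-tailed p is for the
#' direction `r1 > r2`. A naive independent-samples variant (two
#' independent Fisher z's) is available for comparison; it is *not*
#' appropriate for correlations sharing a variable.
#'
#' @param r1,r2 correlations of the two methods with the common reference
#'   (each strictly inside (-1, 1)).
#' @param r12 correlation between the two methods (|r12| < 1).
#' @param n sample size (>= 4).
#' @param method `"meng"` (default) or `"independent"`.
#' @return List of class `cor_comparison` with `r1`, `r2`, `r12`, `n`,
#'   `z`, `p_one_tailed`, `method`.
#' @export
compare_dependent_correlations <- function(r1, r2, r12, n,
                                           method = c("meng", "independent")) {
  method <- match.arg(method)
  if (any(abs(c(r1, r2)) >= 1)) stop("|r1| and |r2| must be < 1")
  if (abs(r12) >= 1) stop("|r12| must be < 1")
  if (n < 4L) stop("n must be at least 4")
  dz <- atanh(r1) - atanh(r2)
  z <- if (method == "meng") {
    rbar2 <- (r1^2 + r2^2) / 2
    f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
    h <- (1 - f * rbar2) / (1 - rbar2)
    dz * sqrt((n - 3) / (2 * (1 - r12) * h))
  } else {
    dz / sqrt(2 / (n - 3))
  }
  structure(list(r1 = r1, r2 = r2, r12 = r12, n = as.integer(n), z = z,
                 p_one_tailed = stats::pnorm(z, lower.tail = FALSE),
                 method = method),
            class = "cor_comparison")
}

#' @export
print.cor_comparison <- function(x, ...) {
  cat(sprintf(
    "Dependent correlation comparison (%s): r1=%.3f r2=%.3f r12=%.3f n=%d\n",
    x$method, x$r1, x$r2, x$r12, x$n))
  cat(sprintf("  z = %.3f, one-tailed p = %.4g (H1: r1 > r2)\n",
              x$z, x$p_one_tailed))
  invisible(x)
}

#' Paired t test
#'
#' Standard paired t on the differences `x - y`, two-tailed, with `n - 1`
#' degrees of freedom. Identical vectors return `t = 0`; constant non-zero
#' differences are an error rather than an infinite statistic.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p_two_tailed`, `mean_difference`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0))                     # identical vectors: no effect at all
      return(list(t = 0, df = length(x) - 1L, p_two_tailed = 1,
                  mean_difference = 0))
    stop("zero-variance non-zero differences: t undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_tailed = tt$p.value, mean_difference = unname(tt$estimate))
}
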
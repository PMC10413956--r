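# Group-comparison statistics, implemented from first principles.
# Base R provides wilcox.test(), ks.test(), chisq.test() and friends; the
# versions here expose exactly the conventions the pipeline reports
# (unreduced U statistics, pooled-ECDF D, tabulated expected counts) and
# are cross-checked against the base implementations in the test suite.

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' `U1` counts, over all pairs, how often a value of `x` exceeds a value
#' of `y`, with ties counted one half; `U2 = n1*n2 - U1`.  The reported
#' two-sided p-value uses the normal approximation with tie-corrected
#' variance and a 0.5 continuity correction, appropriate at the sample
#' sizes of pooled fix-level analyses.  `U_reported` is `U1` of the
#' first-named sample (the unreduced convention).
#'
#' @param x,y numeric samples.
#' @return list of class `rank_test_result`: `U1`, `U2`, `U_reported`,
#'   `z`, `p`, `medians` (named pair), `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U1 = 0
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  pooled <- c(x, y)
  r <- rank(pooled)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) {
    warning("all values tied across both samples; p = 1")
    z <- 0; p <- 1
  } else {
    dev <- U1 - mu
    dev_cc <- sign(dev) * max(abs(dev) - 0.5, 0) # continuity correction
    z <- dev_cc / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(U1 = U1, U2 = U2, U_reported = U1, z = z, p = p,
                 medians = c(x = stats::median(x), y = stats::median(y)),
                 n1 = n1, n2 = n2),
            class = "rank_test_result")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs, evaluated
#' at every pooled data point.  The p-value uses the asymptotic
#' Kolmogorov distribution with effective sample size
#' `ne = n1*n2/(n1 + n2)`.
#'
#' @param x,y numeric samples.
#' @return list of class `ks_result`: `D`, `p`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  pts <- sort(unique(c(x, y)))
  F1 <- vapply(pts, function(p) mean(x <= p), numeric(1))
  F2 <- vapply(pts, function(p) mean(y <= p), numeric(1))
  D <- max(abs(F1 - F2))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- sqrt(ne) * D
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  p <- min(max(p, 0), 1)
  structure(list(D = D, p = p, n1 = n1, n2 = n2), class = "ks_result")
}

#' Chi-square test on an R x C contingency table
#'
#' Expected counts are the usual product of margins over the total;
#' degrees of freedom `(R-1)(C-1)`.  A warning is issued when any
#' expected count falls below 5.
#'
#' @param tab matrix (or table) of non-negative counts, at least 2 x 2.
#' @return list of class `chi_square_result`: `chi2`, `df`, `p`,
#'   `expected`, `observed`.
#' @examples
#' chi_square_rxc(matrix(c(20, 10, 10, 20), 2))
#' @export
chi_square_rxc <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2L, ncol(tab) >= 2L, all(tab >= 0))
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0)) stop("zero marginal in row(s): ",
                         paste(which(rs == 0), collapse = ", "))
  if (any(cs == 0)) stop("zero marginal in column(s): ",
                         paste(which(cs == 0), collapse = ", "))
  expected <- outer(rs, cs) / sum(tab)
  if (any(expected < 5))
    warning("expected counts below 5; chi-square approximation may be poor")
  chi2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p,
                 expected = expected, observed = tab),
            class = "chi_square_result")
}

#' Two-proportion z test (pooled variance)
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list of class `two_proportion_result`: `z`, `p`,
#'   `p1_hat`, `p2_hat`, `n1`, `n2`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n1 >= 1, n2 >= 1)
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    warning("degenerate pooled proportion (0 or 1); z = 0, p = 1")
    z <- 0; p <- 1
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(z = z, p = p, p1_hat = p1, p2_hat = p2, n1 = n1, n2 = n2),
            class = "two_proportion_result")
}

#' Pearson product-moment correlation
#'
#' @param x,y paired numeric samples of equal length, n >= 3.
#' @return list of class `correlation_result`: `r`, `p` (two-sided, from
#'   `t = r * sqrt((n - 2) / (1 - r^2))`), `n`.
#' @export
pearson_correlation <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in at least one variable")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p = p, n = n), class = "correlation_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %.1f (U2 = %.1f), n = (%d, %d), p = %.4g\n",
              x$U_reported, x$U2, x$n1, x$n2, x$p))
  cat(sprintf("  medians: %.4g vs %.4g\n", x$medians[1], x$medians[2]))
  invisible(x)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, n = (%d, %d), p = %.4g\n",
              x$D, x$n1, x$n2, x$p))
  invisible(x)
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Chi-square: chi2 = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' @export
print.two_proportion_result <- function(x, ...) {
  cat(sprintf("Two-proportion z: %.3f vs %.3f, z = %.3f, p = %.4g\n",
              x$p1_hat, x$p2_hat, x$z, x$p))
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f, n = %d, p = %.4g\n",
              x$r, x$n, x$p))
  invisible(x)
}
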
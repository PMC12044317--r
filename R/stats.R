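#' Pearson correlation with a Fisher-z confidence interval
#'
#' Product-moment correlation, two-sided p-value from the t distribution
#' with n - 2 df, and a confidence interval from the Fisher z
#' transformation, \eqn{\tanh(\mathrm{atanh}\, r \pm z_{\alpha/2} /
#' \sqrt{n-3})}.
#'
#' @param x,y numeric vectors of equal length, n >= 4, finite, each with
#'   nonzero variance.
#' @param level confidence level, default 0.95.
#' @return list of class `"correlationResult"` with `r`, `ci_low`,
#'   `ci_high`, `p`, `n`.
#' @export
pearsonCI <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need n >= 4")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  if (stats::sd(x) == 0) stop("x is degenerate (zero variance)")
  if (stats::sd(y) == 0) stop("y is degenerate (zero variance)")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = level)
  r <- unname(ct$estimate)
  n <- length(x)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2],
                 p = ct$p.value, n = n),
            class = "correlationResult")
}

#' Fisher-z interval for a reported correlation
#'
#' Reconstructs the confidence interval implied by a printed correlation
#' coefficient and sample size, without the raw data.
#'
#' @param r correlation coefficient.
#' @param n sample size (> 3).
#' @param level confidence level.
#' @return numeric(2), lower and upper bounds.
#' @examples
#' fisherCI(0.14, 637)  # about (0.062, 0.215)
#' @export
fisherCI <- function(r, n, level = 0.95) {
  stopifnot(abs(r) < 1, n > 3)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
}

#' Average variance extracted between two measures
#'
#' The shared-variance measure used for discriminant validity: the sample
#' covariance of the two variables divided by half the sum of their sample
#' variances (n - 1 denominators throughout). Values below 0.5 indicate
#' that most of the variance of the two indicators is not common.
#'
#' @param x,y numeric vectors of equal length, n >= 2.
#' @return list of class `"aveResult"` with `ave`, `cov`, `var_x`, `var_y`
#'   and the interpretation flag `below_threshold` (`ave < 0.5`).
#' @examples
#' avgVarianceExtracted(c(1, 2, 3), c(2, 4, 6))$ave  # 0.8
#' @export
avgVarianceExtracted <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need n >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) stop("both variables are degenerate (zero variance)")
  cv <- stats::cov(x, y)
  ave <- cv / ((vx + vy) / 2)
  structure(list(ave = ave, cov = cv, var_x = vx, var_y = vy,
                 below_threshold = ave < 0.5),
            class = "aveResult")
}

#' Likelihood-ratio test of a constrained correlation
#'
#' Tests whether the correlation of a bivariate-normal pair equals `rho0`
#' by comparing the maximised likelihood with the correlation constrained
#' to `rho0` against the unconstrained fit. Profiling out the means and
#' variances gives the closed form
#' \deqn{\chi^2 = n \log\frac{(1 - \rho_0 r)^2}{(1 - r^2)(1 - \rho_0^2)}}
#' with r the sample correlation, referred to a chi-square with 1 df.
#' A boundary value `rho0 = ±1` makes the constrained covariance singular
#' and is capped at ±(1 − 1e−6); the cap is reported in the result.
#'
#' @param x,y numeric vectors, n >= 10.
#' @param rho0 correlation under the null, in \[-1, 1\].
#' @return list of class `"lrtResult"` with `chi2`, `df`, `p`, `r`,
#'   `rho0` (after capping) and `capped`.
#' @export
lrtCorrelation <- function(x, y, rho0) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 10L) stop("need n >= 10")
  if (abs(rho0) > 1) stop("rho0 must lie in [-1, 1]")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate data: zero variance")
  capped <- abs(rho0) == 1
  if (capped) rho0 <- sign(rho0) * (1 - 1e-6)
  r <- stats::cor(x, y)
  ## cap a collinear sample at the same epsilon as the boundary null, so
  ## that exactly collinear data are consistent with rho0 = 1 (chi2 = 0)
  if (abs(r) >= 1 - 1e-6) r <- sign(r) * (1 - 1e-6)
  chi2 <- n * log((1 - rho0 * r)^2 / ((1 - r^2) * (1 - rho0^2)))
  chi2 <- max(0, chi2)
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 r = r, rho0 = rho0, capped = capped),
            class = "lrtResult")
}

#' Cubic orthogonal-polynomial regression of a log surface on NPRS
#'
#' Fits \eqn{\log(\mathrm{surface} + 1)} (natural log) on an orthonormal
#' degree-3 polynomial basis of the NPRS score (`stats::poly`). With this
#' basis the polynomial columns are centred and mutually orthogonal, so the
#' intercept equals the mean of the log response rather than the prediction
#' at NPRS 0.
#'
#' @param surface nonnegative surfaces (cm^2), the response before the
#'   log(x + 1) transform.
#' @param nprs pain scores in \[0, 10\], same length, n > 5.
#' @return list of class `"polyFitResult"` with `coefficients` (intercept +
#'   3 polynomial terms), `ci` (95 percent), `p`, `r2`, `n` and the fitted
#'   `lm` object as `fit`.
#' @export
cubicLogFit <- function(surface, nprs) {
  if (length(surface) != length(nprs)) stop("lengths differ")
  if (length(surface) <= 5L) stop("need n > 5")
  if (any(surface < 0)) stop("surfaces must be >= 0")
  if (any(nprs < 0 | nprs > 10)) stop("nprs must lie in [0, 10]")
  y <- log(surface + 1)
  if (length(unique(nprs)) < 4L)
    stop("need at least 4 distinct NPRS values for a cubic basis")
  fit <- stats::lm(y ~ stats::poly(nprs, 3))
  cf <- stats::coef(fit)
  names(cf) <- c("intercept", "degree1", "degree2", "degree3")
  ci <- stats::confint(fit)
  rownames(ci) <- names(cf)
  sm <- summary(fit)
  p <- sm$coefficients[, 4]
  names(p) <- names(cf)
  ## robust R^2: a constant response explains nothing, not NaN
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= 1e-10 * max(1, mean(y)^2)) 0 else
    max(0, min(1, 1 - sum(stats::residuals(fit)^2) / tss))
  structure(list(coefficients = cf, ci = ci, p = p,
                 r2 = r2, n = length(y), fit = fit),
            class = "polyFitResult")
}

#' LOESS curve of y on x
#'
#' Tricube-weighted local linear smoothing (`stats::loess`, degree 1,
#' Gaussian family, direct surface) evaluated on a grid.
#'
#' @param x,y numeric vectors, n >= 20.
#' @param span smoothing span in (0, 1\].
#' @param grid evaluation points; default 100 equally spaced over
#'   `range(x)`.
#' @return data.frame with columns `x` and `fitted`.
#' @export
loessCurve <- function(x, y, span = 0.75,
                       grid = seq(min(x), max(x), length.out = 100)) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 20L) stop("need n >= 20")
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    stop("span must lie in (0, 1]")
  fit <- stats::loess(y ~ x, span = span, degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  data.frame(x = grid, fitted = stats::predict(fit, newdata =
                                                 data.frame(x = grid)))
}

## Jonckheere-Terpstra statistic: sum over ordered group pairs i < j of the
## Mann-Whitney count of (x_i, x_j) pairs with x_j > x_i, ties counted 1/2.
.jtStatistic <- function(values, grp, k) {
  jt <- 0
  for (i in seq_len(k - 1L)) {
    xi <- values[grp == i]
    for (j in (i + 1L):k) {
      xj <- values[grp == j]
      if (length(xi) && length(xj)) {
        d <- outer(xj, xi, "-")
        jt <- jt + sum(d > 0) + 0.5 * sum(d == 0)
      }
    }
  }
  jt
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend of a response across ordered groups. The
#' statistic is the sum of pairwise Mann-Whitney counts over all ordered
#' group pairs, ties counted one half. The p-value uses the tie-corrected
#' normal approximation; `method = "permutation"` instead permutes group
#' labels (full enumeration when the total sample size is at most 10,
#' Monte-Carlo otherwise).
#'
#' @param groups list of numeric vectors in the hypothesised order.
#' @param alternative `"increasing"` (response grows along the group order)
#'   or `"decreasing"`.
#' @param method `"normal"` or `"permutation"`.
#' @param nperm Monte-Carlo permutation count (default 10000).
#' @return list of class `"trendTestResult"` with `jt`, `z`, `p` (one
#'   sided), `method`, `n` (group sizes).
#' @examples
#' jonckheereTest(list(c(1, 2), c(3, 4), c(5, 6)))$jt  # 12, fully concordant
#' @export
jonckheereTest <- function(groups, alternative = c("increasing", "decreasing"),
                           method = c("normal", "permutation"),
                           nperm = 10000) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need an ordered list of at least 2 groups")
  if (any(!vapply(groups, length, 1L)))
    stop("all groups must be non-empty")
  if (alternative == "decreasing") groups <- rev(groups)
  k <- length(groups)
  values <- unlist(groups, use.names = FALSE)
  grp <- rep.int(seq_len(k), vapply(groups, length, 1L))
  ni <- tabulate(grp, k)
  N <- length(values)
  jt <- .jtStatistic(values, grp, k)
  mu <- (N^2 - sum(ni^2)) / 4
  tj <- table(values)
  ## tie-corrected null variance (Hollander & Wolfe)
  A <- N * (N - 1) * (2 * N + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  B <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
  C <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
  v <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) + C / (8 * N * (N - 1))
  z <- (jt - mu) / sqrt(v)
  if (method == "normal") {
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    p <- .jtPermutationP(values, grp, k, ni, jt, nperm)
  }
  structure(list(jt = jt, z = z, p = p, method = method, n = ni,
                 alternative = alternative),
            class = "trendTestResult")
}

## One-sided permutation p-value, P(JT* >= JT_obs). Full enumeration of the
## distinct label arrangements when N <= 10, Monte-Carlo otherwise.
.jtPermutationP <- function(values, grp, k, ni, jt_obs, nperm) {
  N <- length(values)
  if (N <= 10L) {
    ## enumerate all assignments of observation indices to groups
    stats_all <- numeric(0)
    rec <- function(avail, gi, g) {
      if (gi > k) {
        stats_all[length(stats_all) + 1L] <<- .jtStatistic(values, g, k)
        return(invisible())
      }
      picks <- utils::combn(avail, ni[gi], simplify = FALSE)
      for (p in picks) {
        g[p] <- gi
        rec(setdiff(avail, p), gi + 1L, g)
      }
    }
    rec(seq_len(N), 1L, integer(N))
    mean(stats_all >= jt_obs - 1e-9)
  } else {
    exceed <- 0L
    for (b in seq_len(nperm)) {
      gp <- sample(grp)
      if (.jtStatistic(values, gp, k) >= jt_obs - 1e-9) exceed <- exceed + 1L
    }
    (1 + exceed) / (nperm + 1)
  }
}

#' Distribution of the number of colors used
#'
#' @param colorCounts integer vector of per-patient color counts (0..4), or
#'   a cohort data.frame with a `color_count` column.
#' @return list with `proportions` (named, over 0..4), `counts`, and
#'   `multi_rate`, the proportion of patients using 2 or more colors.
#' @export
colorUsageRates <- function(colorCounts) {
  if (is.data.frame(colorCounts)) colorCounts <- colorCounts$color_count
  if (!length(colorCounts)) stop("empty cohort")
  if (any(!colorCounts %in% 0:4)) stop("color counts must lie in 0..4")
  counts <- vapply(0:4, function(k) sum(colorCounts == k), 0L)
  names(counts) <- as.character(0:4)
  list(proportions = counts / length(colorCounts), counts = counts,
       multi_rate = sum(counts[c("2", "3", "4")]) / length(colorCounts))
}

#' Variance in y explained by x, with a bootstrap interval
#'
#' Simple linear regression R-squared of `y` on `x` with a percentile
#' bootstrap confidence interval over case resampling.
#'
#' @param x,y numeric vectors, n >= 10.
#' @param nBoot bootstrap replicates (default 2000).
#' @param level confidence level.
#' @return list with `r2`, `ci_low`, `ci_high`, `n_boot`.
#' @export
varianceExplained <- function(x, y, nBoot = 2000, level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 10L) stop("need n >= 10")
  r2fun <- function(xx, yy) {
    if (stats::sd(xx) == 0 || stats::sd(yy) == 0) return(NA_real_)
    stats::cor(xx, yy)^2
  }
  r2 <- r2fun(x, y)
  boot <- vapply(seq_len(nBoot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    r2fun(x[i], y[i])
  }, 0)
  qs <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(r2 = r2, ci_low = qs[1], ci_high = qs[2], n_boot = nBoot)
}

#' @export
print.correlationResult <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, 95%% CI (%.3f, %.3f), p = %.3g, n = %d\n",
              x$r, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' @export
print.aveResult <- function(x, ...) {
  cat(sprintf("AVE = %.4g (cov %.4g over mean variance %.4g); %s\n",
              x$ave, x$cov, (x$var_x + x$var_y) / 2,
              if (x$below_threshold)
                "below 0.5: mostly non-shared variance" else ">= 0.5"))
  invisible(x)
}

#' @export
print.lrtResult <- function(x, ...) {
  cat(sprintf("LRT chi2(1) = %.3f, p = %.3g (r = %.3f vs rho0 = %.6f%s)\n",
              x$chi2, x$p, x$r, x$rho0,
              if (x$capped) ", boundary-capped" else ""))
  invisible(x)
}

#' @export
print.trendTestResult <- function(x, ...) {
  cat(sprintf("Jonckheere-Terpstra: JT = %.1f, z = %.3f, one-sided p = %.3g (%s, %s)\n",
              x$jt, x$z, x$p, x$alternative, x$method))
  invisible(x)
}

#' @export
print.polyFitResult <- function(x, ...) {
  cat("Cubic orthogonal-polynomial fit of log(surface + 1) on NPRS\n")
  for (nm in names(x$coefficients))
    cat(sprintf("  %-10s %7.3f  (%.3f, %.3f)  p = %.3g\n", nm,
                x$coefficients[nm], x$ci[nm, 1], x$ci[nm, 2], x$p[nm]))
  cat(sprintf("  R^2 = %.4f on n = %d\n", x$r2, x$n))
  invisible(x)
}
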
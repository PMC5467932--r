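#' Two-sample t test from summary statistics
#'
#' Computes the Welch (default) or pooled-variance two-sample t test
#' directly from each group's mean, standard deviation and size -- the form
#' needed to re-test published group summaries. On summaries computed from
#' raw samples this is exactly equivalent to the raw-data test.
#'
#' @param m1,s1,n1 mean, SD and size of group 1 (`n1 >= 2`, `s1 >= 0`).
#' @param m2,s2,n2 same for group 2.
#' @param method `"welch"` (unequal variances, Welch-Satterthwaite df) or
#'   `"pooled"` (classical equal-variance test).
#' @param conf_level confidence level for the mean-difference interval.
#' @return an object of class `stat_result`: `statistic` (t), `df`
#'   (possibly fractional), `p_two_sided`, `estimate` (m1 - m2), `ci_95`,
#'   `method`, `p_display` (journal-style rounding, see [format_p()]).
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                method = c("welch", "pooled"),
                                conf_level = 0.95) {
  method <- match.arg(method)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  est <- m1 - m2
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) {
      res <- list(statistic = 0, df = n1 + n2 - 2, p_two_sided = 1,
                  estimate = 0, ci_95 = c(0, 0), method = method)
      res$p_display <- format_p(1)
      class(res) <- "stat_result"
      return(res)
    }
    stop("both groups have zero variance but different means: t undefined",
         call. = FALSE)
  }
  if (method == "welch") {
    se2 <- s1^2 / n1 + s2^2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  res <- list(statistic = tval, df = df, p_two_sided = p, estimate = est,
              ci_95 = c(est - tcrit * se, est + tcrit * se), method = method,
              p_display = format_p(p))
  class(res) <- "stat_result"
  res
}

#' @export
print.stat_result <- function(x, ...) {
  if (x$method %in% c("welch", "pooled"))
    cat(sprintf("<stat_result> %s t = %.3f, df = %.2f, p = %.4g (display %s), diff %.4g [%.4g, %.4g]\n",
                x$method, x$statistic, x$df, x$p_two_sided, x$p_display,
                x$estimate, x$ci_95[1], x$ci_95[2]))
  else
    cat(sprintf("<stat_result> Spearman rho = %.3f, n = %d, p = %.4g (display %s)\n",
                x$statistic, x$n, x$p_two_sided, x$p_display))
  invisible(x)
}

#' Journal-style p-value rounding
#'
#' Reproduces the common clinical-journal display convention: one decimal
#' for p >= 0.095, two decimals below that, and two significant digits when
#' two decimals would display as 0.00 (e.g. 0.008, 0.0006).
#'
#' @param p numeric p value(s) in `[0, 1]`.
#' @return numeric rounded value(s).
#' @export
format_p <- function(p) {
  one <- function(pp) {
    if (is.na(pp)) return(NA_real_)
    if (pp >= 0.095) return(round(pp, 1))
    r2 <- round(pp, 2)
    if (r2 >= 0.01) return(r2)
    signif(pp, 2)
  }
  vapply(p, one, numeric(1))
}

#' Spearman rank correlation with pairwise-complete observations
#'
#' Average-rank (tie-aware) Spearman rho on the pairwise-complete subset,
#' with the two-sided p value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df (the convention
#' used in clinical correlation tables), or the exact permutation null for
#' small tie-free samples.
#'
#' @param x,y numeric vectors of equal length; `NA`s are dropped pairwise.
#' @param exact use the exact null distribution (delegated to
#'   [stats::cor.test()]; tie-free samples with n <= 10 only).
#' @return a `stat_result` with `statistic` = rho, `n` = complete pairs,
#'   `p_two_sided`, `method = "spearman"`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  if (exact) {
    if (n > 10) stop("exact permutation p only for n <= 10", call. = FALSE)
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  res <- list(statistic = rho, df = n - 2, n = n, p_two_sided = p,
              method = "spearman", p_display = format_p(p))
  class(res) <- "stat_result"
  res
}

#' Bland-Altman agreement analysis
#'
#' For paired readings of the same quantity: differences
#' `reading1 - reading2`, their mean and SD (n - 1 denominator), the 95%
#' limits of agreement `mean +/- 1.96 SD`, and the Pearson correlation of
#' the two readings.
#'
#' @param reading1,reading2 numeric vectors of paired readings (>= 2
#'   complete pairs).
#' @return an object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `r`, `n`.
#' @export
bland_altman <- function(reading1, reading2) {
  if (length(reading1) != length(reading2))
    stop("readings must be paired", call. = FALSE)
  ok <- stats::complete.cases(reading1, reading2)
  r1 <- reading1[ok]; r2 <- reading2[ok]
  if (length(r1) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- r1 - r2
  m <- mean(d)
  s <- stats::sd(d)
  rr <- if (stats::sd(r1) == 0 || stats::sd(r2) == 0) {
    if (all(r1 == r2)) 1 else NA_real_
  } else stats::cor(r1, r2)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
         r = rr, n = length(r1)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, mean diff %.4g, LoA [%.4g, %.4g], r = %.3f\n",
              x$n, x$mean_diff, x$loa_lower, x$loa_upper, x$r))
  invisible(x)
}

#' Construct a sample with exact mean and SD
#'
#' Rescales a base sample (by default the standard-normal quantile grid) to
#' have exactly the requested first two moments. Used to turn a published
#' (mean, SD, n) summary into a raw sample on which raw-data and
#' summary-statistic tests must agree exactly.
#'
#' @param m,s,n target mean, SD and size (`n >= 2`).
#' @param base optional base sample of length `n` with nonzero spread.
#' @return numeric vector of length `n` with `mean == m`, `sd == s`.
#' @export
moment_matched_sample <- function(m, s, n, base = NULL) {
  if (n < 2) stop("need n >= 2", call. = FALSE)
  x <- base %||% stats::qnorm((seq_len(n) - 0.5) / n)
  if (length(x) != n) stop("base sample must have length n", call. = FALSE)
  sx <- stats::sd(x)
  if (sx == 0) stop("base sample has zero spread", call. = FALSE)
  m + s * (x - mean(x)) / sx
}
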
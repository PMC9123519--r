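# Statistical agreement layer: one-way ICC, Bland-Altman, regression of
# paired differences on a covariate, and minimum detectable difference.

# normalize (a, b) / data frame / n x k matrix input to a numeric matrix
as_rating_matrix <- function(a, b = NULL) {
  if (is.null(b)) {
    if (is.data.frame(a)) {
      cols <- intersect(c("value_a", "value_b"), names(a))
      if (length(cols) == 2L) {
        a <- cbind(a$value_a, a$value_b)
      } else {
        a <- as.matrix(a[vapply(a, is.numeric, logical(1))])
      }
    }
    m <- as.matrix(a)
  } else {
    stopifnot(length(a) == length(b))
    m <- cbind(as.numeric(a), as.numeric(b))
  }
  if (!is.numeric(m) || ncol(m) < 2L) {
    stop("need an n x k (k >= 2) table of ratings", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("ratings must be finite", call. = FALSE)
  unname(m)
}

#' One-way random-effects intraclass correlation
#'
#' ICC from a one-way ANOVA with subjects as the random grouping factor:
#' `(MSB - MSW) / (MSB + (k - 1) * MSW)`, where MSB and MSW are the
#' between- and within-subject mean squares and `k` the number of raters.
#' The 95% confidence interval is the classical F-based (Searle) interval:
#' with `F = MSB/MSW`, the bounds are `(F/Fu - 1)/(F/Fu + k - 1)` and
#' `(F*Fl - 1)/(F*Fl + k - 1)` with `Fu = qf(1 - alpha/2, n-1, n(k-1))`,
#' `Fl = qf(1 - alpha/2, n(k-1), n-1)`.
#'
#' @param a Ratings: an n x k matrix, a data frame with `value_a`/
#'   `value_b` columns, or the first rater's vector (then supply `b`).
#' @param b Optional second rater's vector.
#' @param alpha Two-sided CI level is `1 - alpha`. Default 0.05.
#' @return List of class `icc_result`: `icc`, `lower`, `upper`, `n`, `k`,
#'   `ms_between`, `ms_within`.
#' @export
#' @examples
#' icc_oneway(c(10, 12, 14, 9), c(11, 12, 13, 10))
icc_oneway <- function(a, b = NULL, alpha = 0.05) {
  m <- as_rating_matrix(a, b)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  rm_ <- rowMeans(m)
  gm <- mean(m)
  msb <- k * sum((rm_ - gm)^2) / (n - 1)
  msw <- sum((m - rm_)^2) / (n * (k - 1))
  if (msw == 0 && msb == 0) {
    warning("zero between- and within-subject variance; ICC undefined, returning 1")
    res <- list(icc = 1, lower = NA_real_, upper = NA_real_)
  } else if (msw == 0) {
    warning("zero within-subject variance; ICC = 1 with degenerate CI")
    res <- list(icc = 1, lower = 1, upper = 1)
  } else {
    f <- msb / msw
    fu <- qf(1 - alpha / 2, n - 1, n * (k - 1))
    fl <- qf(1 - alpha / 2, n * (k - 1), n - 1)
    res <- list(icc = (msb - msw) / (msb + (k - 1) * msw),
                lower = (f / fu - 1) / (f / fu + k - 1),
                upper = (f * fl - 1) / (f * fl + k - 1))
  }
  structure(c(res, list(n = n, k = k, ms_between = msb, ms_within = msw,
                        alpha = alpha)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("one-way ICC: %.3f (%d%% CI, %.3f-%.3f), n = %d, k = %d\n",
              x$icc, round(100 * (1 - x$alpha)), x$lower, x$upper, x$n, x$k))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements, computes differences `d = a - b`, the mean bias,
#' 95% limits of agreement `bias +/- 1.96 * SD(d)`, t-based confidence
#' intervals for the bias (`SD/sqrt(n)`) and for each limit (variance
#' `3 * SD^2 / n`, the classical large-sample approximation), and the bias
#' as a percentage of the grand mean.
#'
#' @param a,b Paired measurement vectors (first minus second defines the
#'   difference sign), or a data frame with `value_a`/`value_b` in `a`.
#' @return List of class `agreement_result`: `n`, `bias`, `sd_diff`,
#'   `loa_lo`, `loa_hi`, `ci_bias`, `ci_loa_lo`, `ci_loa_hi`,
#'   `percent_bias`, and a `points` data frame (`mean`, `diff`) for
#'   plotting.
#' @export
#' @examples
#' bland_altman(c(10, 12, 11), c(8, 9, 10))  # bias 2, LoA 0.04-3.96
bland_altman <- function(a, b = NULL) {
  m <- as_rating_matrix(a, b)
  if (ncol(m) != 2L) stop("Bland-Altman needs exactly two columns", call. = FALSE)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- m[, 1] - m[, 2]
  bias <- mean(d)
  s <- sd(d)
  if (s == 0) warning("constant differences; limits of agreement collapse to the bias")
  loa <- bias + c(-1, 1) * 1.96 * s
  tq <- qt(0.975, n - 1)
  ci_bias <- bias + c(-1, 1) * tq * s / sqrt(n)
  half_loa <- tq * sqrt(3 * s^2 / n)
  gm <- mean(c(mean(m[, 1]), mean(m[, 2])))
  structure(list(n = n, bias = bias, sd_diff = s,
                 loa_lo = loa[1], loa_hi = loa[2],
                 ci_bias = ci_bias,
                 ci_loa_lo = loa[1] + c(-1, 1) * half_loa,
                 ci_loa_hi = loa[2] + c(-1, 1) * half_loa,
                 percent_bias = if (gm == 0) NA_real_ else 100 * bias / gm,
                 points = data.frame(mean = rowMeans(m), diff = d)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f (95%% CI %.3f to %.3f)\n",
              x$n, x$bias, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  LoA %.3f to %.3f; percent bias %.1f%%\n",
              x$loa_lo, x$loa_hi, x$percent_bias))
  invisible(x)
}

#' Bias as a percentage of the grand mean
#'
#' `100 * bias / ((mean_a + mean_b) / 2)`. Report rounded to one decimal.
#'
#' @param bias Mean difference (a - b) in metric units.
#' @param mean_a,mean_b The two methods' means.
#' @return Percent bias (unrounded).
#' @export
#' @examples
#' percent_bias(2661, 12375, 9713)  # 24.1 after rounding
percent_bias <- function(bias, mean_a, mean_b) {
  gm <- (mean_a + mean_b) / 2
  if (gm == 0) stop("grand mean is zero; percent bias undefined", call. = FALSE)
  100 * bias / gm
}

#' Regression of paired differences on a covariate
#'
#' Ordinary least squares of `d = a - b` on a per-subject covariate
#' (eccentricity, time between sessions, ...), with the coefficient of
#' determination and the two-sided t-test p-value for the slope.
#'
#' @param a,b Paired measurement vectors.
#' @param covariate Per-subject covariate values.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
diff_vs_covariate <- function(a, b, covariate) {
  m <- as_rating_matrix(a, b)
  stopifnot(length(covariate) == nrow(m))
  if (nrow(m) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (sd(covariate) == 0) stop("constant covariate; slope undefined", call. = FALSE)
  d <- m[, 1] - m[, 2]
  if (sd(d) == 0) {
    # constant differences: flat fit with nothing explained
    return(list(slope = 0, intercept = d[1], r_squared = 0,
                p_value = NA_real_, n = nrow(m)))
  }
  fit <- lm(d ~ covariate)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n = nrow(m))
}

#' Minimum detectable difference as a percentage of the mean
#'
#' Closed-form power calculation: the smallest true difference detectable
#' with the given power at two-sided level `alpha`, expressed as a
#' percentage of the mean. For a two-sample design
#' `delta = (t_{1-alpha/2, 2n-2} + t_{power, 2n-2}) * sd * sqrt(2/n)`; for
#' a paired design `delta = (t_{1-alpha/2, n-1} + t_{power, n-1}) *
#' sd / sqrt(n)`.
#'
#' @param mean Reference mean of the metric.
#' @param sd Its standard deviation (between subjects, or of paired
#'   differences for the paired design).
#' @param n Sample size per group (or number of pairs).
#' @param power Target power, in (0, 1). Default 0.80.
#' @param alpha Two-sided type-I level, in (0, 1). Default 0.05.
#' @param design `"two_sample"` (default) or `"paired"`.
#' @return Minimum detectable difference in percent of `mean`.
#' @export
#' @examples
#' detectable_difference(15528, 1808, 48)  # ~6.7%
detectable_difference <- function(mean, sd, n, power = 0.80, alpha = 0.05,
                                  design = c("two_sample", "paired")) {
  design <- match.arg(design)
  check_positive(mean, "mean")
  if (sd < 0) stop("'sd' must be non-negative", call. = FALSE)
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  if (!(power > 0 && power < 1)) stop("'power' must be in (0, 1)", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (design == "two_sample") {
    df <- 2 * n - 2
    delta <- (qt(1 - alpha / 2, df) + qt(power, df)) * sd * sqrt(2 / n)
  } else {
    df <- n - 1
    delta <- (qt(1 - alpha / 2, df) + qt(power, df)) * sd / sqrt(n)
  }
  100 * delta / mean
}
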
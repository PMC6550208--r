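#' Bland-Altman bias and limits of agreement
#'
#' Differences are taken as `calculated - measured`, so a negative bias means
#' the sensor-calculated volume under-reads the spirometer. Limits of
#' agreement are `bias +/- 1.96 * SD` of the differences (sample SD, n - 1).
#'
#' @param measured,calculated Paired numeric vectors (equal length, n >= 2).
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`, and a
#'   `scatter` data frame (`mean_l`, `diff_l`) for plotting.
#' @examples
#' bland_altman(c(1, 2, 3), c(1.1, 2.1, 3.1))  # constant +0.1 offset
#' @export
bland_altman <- function(measured, calculated) {
  if (length(measured) != length(calculated))
    stop("measured and calculated must have equal length")
  if (length(measured) < 2) stop("need at least 2 pairs")
  d <- calculated - measured
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d),
       scatter = data.frame(mean_l = (measured + calculated) / 2, diff_l = d))
}

#' Lin's concordance correlation coefficient
#'
#' `2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`, penalizing both
#' correlation loss and location/scale shift, so `ccc(x, x + a) < 1` for any
#' nonzero offset `a` (unlike the Pearson correlation). Lin's original
#' definition uses population (1/n) moments; set `moments = "sample"` for
#' the n-1 variant.
#'
#' @param x,y Paired numeric vectors (equal length, n >= 2, not both
#'   constant).
#' @param moments `"population"` (default) or `"sample"`.
#' @return Coefficient in `[-1, 1]`.
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7: perfect correlation, shifted location
#' @export
ccc <- function(x, y, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  mx <- mean(x); my <- mean(y)
  denom_n <- if (moments == "population") n else n - 1
  sx2 <- sum((x - mx)^2) / denom_n
  sy2 <- sum((y - my)^2) / denom_n
  sxy <- sum((x - mx) * (y - my)) / denom_n
  if (sx2 == 0 && sy2 == 0)
    stop("concordance undefined: both series are constant")
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' One-way ANOVA on groups of breath periods
#'
#' Classical one-way F statistic (between-group over within-group mean
#' squares) and its p-value, used to test whether periods measured by the
#' strain sensors and the spirometer differ. Cleanly separated groups with
#' zero within-group variance yield `F = Inf`, `p = 0`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `f`, `p`, `df_between`, `df_within`.
#' @export
anova_periods <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values")
  k <- length(groups)
  n_i <- vapply(groups, length, integer(1))
  n <- sum(n_i)
  m_i <- vapply(groups, mean, numeric(1))
  grand <- sum(n_i * m_i) / n
  ss_between <- sum(n_i * (m_i - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- k - 1
  df_w <- n - k
  if (ss_within == 0) {
    f <- if (ss_between == 0) 0 else Inf
    p <- if (ss_between == 0) 1 else 0
  } else {
    f <- (ss_between / df_b) / (ss_within / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  list(f = f, p = p, df_between = df_b, df_within = df_w)
}

#' Method-agreement report for measured vs calculated volumes
#'
#' Bundles the Bland-Altman bias/limits of agreement and Lin's concordance
#' correlation coefficient for a measured/calculated volume pairing.
#'
#' @param measured,calculated Paired volumes, L.
#' @param direction Label (`"exhale"` / `"inhale"`) recorded in the report.
#' @return Object of class `agreement_report` with `bias`, `loa_low`,
#'   `loa_high`, `ccc`, `n`, `direction`, `diff_direction`
#'   (`"calculated - measured"`), and the Bland-Altman `scatter`.
#' @export
agreement_report <- function(measured, calculated, direction = "exhale") {
  ba <- bland_altman(measured, calculated)
  out <- list(bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
              ccc = ccc(measured, calculated), n = ba$n,
              direction = direction,
              diff_direction = "calculated - measured",
              scatter = ba$scatter)
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s volume, n = %d breaths\n",
              x$direction, x$n))
  cat(sprintf("  bias (%s) = %.3f L, LoA [%.3f, %.3f] L\n",
              x$diff_direction, x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  concordance correlation = %.3f\n", x$ccc))
  invisible(x)
}

#' Serialize an agreement report to JSON
#'
#' @param report An `agreement_report`.
#' @param path File path; the Bland-Altman scatter is omitted (export it
#'   separately with [write.csv()] if needed).
#' @return `path`, invisibly.
#' @export
write_agreement <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  obj <- report[c("bias", "loa_low", "loa_high", "ccc", "n", "direction",
                  "diff_direction")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
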
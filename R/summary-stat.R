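#' Convert a 95% confidence-interval half-width to a standard deviation
#'
#' Published single-cell timing tables report `mean +/- half` where the
#' `+/-` value is the half-width of a normal-theory 95% confidence interval
#' of the mean over `n` cells.  The underlying per-cell standard deviation is
#' recovered as `half * sqrt(n) / 1.96` (z = 1.96; the tables assume
#' normality, so no t-quantile is used).
#'
#' @param half_width CI half-width, in the native units of the measurement.
#' @param n number of cells the mean was computed over.
#' @return standard deviation in the same units as `half_width`.
#' @examples
#' sd_from_ci95(4, 100)   # 20.408...
#' sd_from_ci95(7, 100)   # 35.714...
#' @export
sd_from_ci95 <- function(half_width, n) {
  if (!is.numeric(half_width) || any(!is.finite(half_width)) || any(half_width < 0)) {
    stop("`half_width` must be finite and >= 0")
  }
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    stop("`n` must be >= 1")
  }
  half_width * sqrt(n) / 1.96
}

#' Summary statistic: mean, 95% CI half-width, n, and derived SD
#'
#' Container mirroring the `mean +/- ci` convention of the event-timing
#' tables.  The per-cell SD is always derived from the CI half-width via
#' [sd_from_ci95()], so the three stored fields stay mutually consistent.
#'
#' @param mean sample mean (native units).
#' @param ci95_half 95% CI half-width of the mean (same units).
#' @param n sample size.
#' @return an object of class `summary_stat` with fields `mean`,
#'   `ci95_half`, `n`, `sd`.
#' @examples
#' summary_stat(252, 7, 100)
#' @export
summary_stat <- function(mean, ci95_half, n) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (!is_count(n)) stop("`n` must be a positive integer")
  if (!is.numeric(ci95_half) || length(ci95_half) != 1L ||
      !is.finite(ci95_half) || ci95_half < 0) {
    stop("`ci95_half` must be finite and >= 0")
  }
  structure(
    list(mean = mean, ci95_half = ci95_half, n = as.integer(n),
         sd = sd_from_ci95(ci95_half, n)),
    class = "summary_stat"
  )
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("%g ± %g (n = %d, sd = %.4g)\n",
              x$mean, x$ci95_half, x$n, x$sd))
  invisible(x)
}

#' @export
format.summary_stat <- function(x, ...) {
  sprintf("%g ± %g (n=%d)", x$mean, x$ci95_half, x$n)
}

#' Mean and normal-theory 95% confidence interval of a sample
#'
#' The summary convention used throughout the single-cell analysis:
#' sample mean, CI half-width `1.96 * sd / sqrt(n)` with the `n - 1`
#' denominator in the sample SD, and the SD itself.
#'
#' @param values numeric vector of measurements, `length >= 2`, all finite.
#' @return a [summary_stat()] (its `sd` field equals the sample SD).
#' @examples
#' mean_ci95(c(1, 2, 3, 4, 5))
#' @export
mean_ci95 <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("need at least 2 finite values")
  }
  if (any(!is.finite(values))) stop("all values must be finite")
  n <- length(values)
  s <- stats::sd(values)
  summary_stat(mean(values), 1.96 * s / sqrt(n), n)
}
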
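#' Construct a kill curve
#'
#' An OD600 time series from a Bioscreen-style predation assay: optical
#' density of a prey suspension read on a fixed time grid (the assays use
#' 20-min intervals over 42 h) while predators lyse the prey.
#'
#' @param time_min reading times in minutes, strictly increasing, `>= 0`.
#' @param od600 OD600 readings, same length, finite.
#' @param species,replicate optional labels.
#' @return a data frame of class `kill_curve` with columns `time_min`,
#'   `od600` (and the labels, if given).
#' @export
kill_curve <- function(time_min, od600, species = NULL, replicate = NULL) {
  if (length(time_min) != length(od600)) stop("time_min and od600 lengths differ")
  if (any(!is.finite(time_min)) || any(time_min < 0)) stop("times must be finite and >= 0")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(od600))) stop("od600 must be finite")
  df <- data.frame(time_min = as.numeric(time_min), od600 = as.numeric(od600))
  if (!is.null(species)) df$species <- species
  if (!is.null(replicate)) df$replicate <- replicate
  structure(df, class = c("kill_curve", "data.frame"))
}

#' Four-parameter Weibull decay model
#'
#' The type-1 four-parameter Weibull dose-response curve in its
#' time-response form,
#' \deqn{f(t) = c + (d - c)\,\exp\{-\exp[b(\ln t - \ln e)]\},}
#' with slope `b` (> 0 for a decay), lower asymptote `c`, upper asymptote
#' `d`, and scale/inflection time `e` (> 0, minutes).  `f(0)` is defined as
#' `d` by continuity when `b > 0`.
#'
#' @param t time(s) in minutes, `>= 0`.
#' @param b,c,d,e model parameters.
#' @return OD600 value(s).
#' @examples
#' weibull4(1000, b = 1, c = 0, d = 1, e = 1000)  # 1/e below d: 0.3679
#' @export
weibull4 <- function(t, b, c, d, e) {
  if (!is.finite(e) || e <= 0) stop("scale parameter e must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  out <- c + (d - c) * exp(-exp(b * (log(t) - log(e))))
  if (any(t == 0)) out[t == 0] <- if (b > 0) d else c
  out
}

#' Fit the four-parameter Weibull model to a kill curve
#'
#' Nonlinear least squares by bounded Levenberg-Marquardt.  The
#' initialization is deterministic: `d0 = max(od)`, `c0 = min(od)`, `e0` the
#' time whose OD is nearest `(c0 + d0)/2`, `b0 = 1`; `b` and `e` are bounded
#' below by a small positive value.  Degenerate data (constant OD) yield
#' `converged = FALSE` with a diagnostic, never an error.
#'
#' @param curve a [kill_curve()] (or data frame with `time_min`, `od600`);
#'   at least 6 points spanning a decline.
#' @return an object of class `weibull_fit` with fields `b`, `c`, `d`, `e`,
#'   `rss`, `n_points`, `converged` (and `diagnostic` when not converged).
#' @export
fit_weibull4 <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("time_min", "od600") %in% names(curve)))
  t <- curve$time_min
  od <- curve$od600
  if (length(t) < 6L) stop("need at least 6 points to fit the four-parameter model")
  unconverged <- function(msg) {
    structure(list(b = NA_real_, c = min(od), d = max(od), e = NA_real_,
                   rss = sum((od - mean(od))^2), n_points = length(od),
                   converged = FALSE, diagnostic = msg),
              class = "weibull_fit")
  }
  if (stats::sd(od) == 0) return(unconverged("constant OD: no decline to fit"))
  d0 <- max(od)
  c0 <- min(od)
  e0 <- t[which.min(abs(od - (c0 + d0) / 2))]
  if (e0 <= 0) e0 <- min(t[t > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      od ~ weibull4(t, b, c, d, e),
      start = list(b = 1, c = c0, d = d0, e = e0),
      lower = c(b = 1e-6, c = -Inf, d = -Inf, e = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) return(unconverged(conditionMessage(fit)))
  cf <- stats::coef(fit)
  structure(list(b = unname(cf["b"]), c = unname(cf["c"]), d = unname(cf["d"]),
                 e = unname(cf["e"]), rss = sum(stats::resid(fit)^2),
                 n_points = length(od), converged = TRUE),
            class = "weibull_fit")
}

#' Effective kill time
#'
#' Time at which a fraction `fraction` of the prey's OD signal has been
#' lost, i.e. the relative response `(f(t) - c)/(d - c)` has fallen to
#' `1 - fraction`.  For the four-parameter Weibull decay this has the
#' closed form
#' \deqn{EKT_q = e\,\exp\{\ln[-\ln(1 - q)] / b\},}
#' so `EKT50 = e * exp(log(log(2))/b)` (= `e * log(2)` when `b = 1`).
#'
#' @param fit a converged [fit_weibull4()] result with `b > 0` (or any list
#'   with fields `b` and `e`, e.g. known true parameters).
#' @param fraction killed fraction `q`, `0 < q < 1` (default 0.5: EKT50).
#' @return time in minutes.
#' @examples
#' ekt(list(b = 1, e = 1000, converged = TRUE))  # 693.15
#' @export
ekt <- function(fit, fraction = 0.5) {
  if (!is.null(fit$converged) && !isTRUE(fit$converged)) {
    stop("cannot compute an effective kill time from an unconverged fit")
  }
  if (!is.finite(fit$b) || fit$b <= 0) stop("requires slope b > 0")
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)")
  }
  fit$e * exp(log(-log(1 - fraction)) / fit$b)
}

#' @export
print.weibull_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<weibull_fit: b = %.4g, c = %.4g, d = %.4g, e = %.4g min; rss = %.3g, n = %d>\n",
      x$b, x$c, x$d, x$e, x$rss, x$n_points))
    cat(sprintf("  EKT50 = %.4g min\n", ekt(x)))
  } else {
    cat(sprintf("<weibull_fit: NOT converged (%s), n = %d>\n",
                x$diagnostic, x$n_points))
  }
  invisible(x)
}
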
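#' Gamma probability-density kernel of the cortisol response curve
#'
#' The structural shape of the cortisol stress response is the density of a
#' gamma distribution with shape `alpha` and rate `beta` (per minute).
#' The density is defined as 0 for `x <= 0`: the modelled response begins at
#' stressor onset.
#'
#' @param x Numeric vector, time in minutes.
#' @param alpha Shape parameter, `> 0` (unitless).
#' @param beta Rate parameter, `> 0` (1/min).
#' @return Numeric vector of density values; 0 wherever `x <= 0`.
#' @examples
#' gamma_density(1, alpha = 1, beta = 1)  # exp(-1)
#' @export
gamma_density <- function(x, alpha, beta) {
  if (!is_scalar_number(alpha) || alpha <= 0) {
    stop("`alpha` must be a positive number", call. = FALSE)
  }
  if (!is_scalar_number(beta) || beta <= 0) {
    stop("`beta` must be a positive number", call. = FALSE)
  }
  out <- numeric(length(x))
  pos <- is.finite(x) & x > 0
  out[pos] <- stats::dgamma(x[pos], shape = alpha, rate = beta)
  out[!is.finite(x)] <- NA_real_
  out
}

#' Construct a cortisol response curve
#'
#' A response curve is the gamma kernel scaled and shifted:
#' `g(t) = A * f(t - dT) + b0 + b1 * (t - dT)`, where `f` is the gamma
#' density with parameters `alpha` and `beta`. With `b1 = 0`, `dT = 0` this
#' reduces to `g(t) = A * f(t) + b0`.
#'
#' @param alpha,beta Gamma kernel shape and rate (`> 0`).
#' @param A Amplitude in nmol/L * min. Non-negative for fitted stress
#'   responses; any real value is allowed so that declining control
#'   profiles can be represented by amplitude scaling.
#' @param b0 Baseline cortisol level in nmol/L.
#' @param b1 Linear drift in nmol/L per minute (diurnal trend), default 0.
#' @param dT Time shift in minutes (moves response onset and peak), default 0.
#' @return An object of class `response_curve`.
#' @examples
#' crv <- response_curve(alpha = 3, beta = 0.1, A = 150, b0 = 5)
#' eval_curve(crv, c(0, 10, 20, 40))
#' @export
response_curve <- function(alpha, beta, A, b0 = 0, b1 = 0, dT = 0) {
  if (!is_scalar_number(alpha) || alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (!is_scalar_number(beta) || beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  for (nm in c("A", "b0", "b1", "dT")) {
    v <- get(nm)
    if (!is_scalar_number(v)) stop("`", nm, "` must be a finite number", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, A = A, b0 = b0, b1 = b1, dT = dT),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat("Cortisol response curve: g(t) = A * f(t - dT) + b0 + b1 (t - dT)\n")
  cat(sprintf("  alpha = %.4g, beta = %.4g /min, A = %.4g, b0 = %.4g nmol/L",
              x$alpha, x$beta, x$A, x$b0))
  if (x$b1 != 0 || x$dT != 0) {
    cat(sprintf(", b1 = %.4g, dT = %.4g min", x$b1, x$dT))
  }
  cat("\n")
  invisible(x)
}

#' Regular time grid in minutes
#'
#' @param start,stop Window ends in minutes relative to stressor onset.
#' @param step Grid step in minutes (default 1).
#' @return Numeric vector including both endpoints whenever
#'   `(stop - start)` is an integer multiple of `step`.
#' @export
time_grid <- function(start, stop, step = 1) {
  if (start > stop) stop("`start` must be <= `stop`", call. = FALSE)
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  n <- floor((stop - start) / step + 1e-9)
  start + step * (0:n)
}

#' Evaluate a response curve at given times
#'
#' @param curve A [response_curve()].
#' @param times Numeric vector of times in minutes relative to stressor onset.
#' @return Numeric vector of cortisol values (nmol/L), same length as `times`.
#' @export
eval_curve <- function(curve, times) {
  stopifnot(inherits(curve, "response_curve"))
  if (length(times) == 0) return(numeric(0))
  x <- times - curve$dT
  curve$A * gamma_density(x, curve$alpha, curve$beta) + curve$b0 + curve$b1 * x
}

#' @export
predict.response_curve <- function(object, times = time_grid(0, 80), ...) {
  eval_curve(object, times)
}

#' Locate the peak of a response curve
#'
#' The maximum of the curve over `window` is found on a regular search grid
#' (0.1 min by default), with ties broken to the earliest time. For the
#' unshifted, drift-free curve with `alpha > 1` the peak is the gamma mode
#' `(alpha - 1) / beta`.
#'
#' @param curve A [response_curve()].
#' @param window Length-2 numeric search window in minutes.
#' @param step Search grid step in minutes.
#' @return List with `t_peak` (min) and `value` (nmol/L).
#' @export
curve_peak <- function(curve, window = c(0, 80), step = 0.1) {
  stopifnot(inherits(curve, "response_curve"))
  if (curve$A == 0 && curve$b1 == 0) {
    stop("flat curve (A = 0, b1 = 0) has no peak", call. = FALSE)
  }
  grid <- time_grid(window[1], window[2], step)
  vals <- eval_curve(curve, grid)
  i <- which.max(vals) # earliest index on ties
  list(t_peak = grid[i], value = vals[i])
}

#' Analytic area under a response curve
#'
#' Closed-form integral of the curve over `(t0, t1)` using the gamma CDF:
#' `A * (F(t1 - dT) - F(t0 - dT)) + b0 * (t1 - t0) +
#'  b1 * ((t1 - dT)^2 - (t0 - dT)^2) / 2`.
#'
#' @param curve A [response_curve()].
#' @param window Length-2 numeric integration window `(t0, t1)`, `t0 < t1`.
#' @return Area in nmol/L * min.
#' @export
curve_auc <- function(curve, window = c(0, 80)) {
  stopifnot(inherits(curve, "response_curve"))
  t0 <- window[1]; t1 <- window[2]
  if (!(t0 < t1)) stop("degenerate window: need t0 < t1", call. = FALSE)
  x0 <- t0 - curve$dT; x1 <- t1 - curve$dT
  cdf <- function(x) {
    ifelse(x <= 0, 0, stats::pgamma(x, shape = curve$alpha, rate = curve$beta))
  }
  curve$A * (cdf(x1) - cdf(x0)) + curve$b0 * (t1 - t0) +
    curve$b1 * (x1^2 - x0^2) / 2
}

#' @export
plot.response_curve <- function(x, window = c(0, 80), step = 0.5, ...,
                                xlab = "Time since stressor onset (min)",
                                ylab = "Cortisol (nmol/L)", type = "l") {
  grid <- time_grid(window[1], window[2], step)
  plot(grid, eval_curve(x, grid), type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
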
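# Amplitude scaling model: a single population-average gamma-shaped
# response curve fitted on stress-condition responders, rescaled per
# individual by a single amplitude parameter.

pop_start_values <- function(t, y, b0) {
  alpha0 <- 3; beta0 <- 0.1
  fmax <- gamma_density((alpha0 - 1) / beta0, alpha0, beta0)
  A0 <- max(max(y) - b0, 0.5) / fmax
  list(lalpha = log(alpha0), lbeta = log(beta0), A = A0)
}

#' Fit the population-average cortisol response curve
#'
#' Pooled nonlinear least squares of `g(t) = A * f(t) + b0` over all
#' samples, with the baseline `b0` fixed (not estimated) to the mean
#' cortisol value of the fitting sample at `t = 0`. The fitting sample
#' should contain stress-condition responders only; see [fit_asm()] for
#' the full pipeline. With `extended = TRUE` the time-shift `dT` and drift
#' `b1` parameters are estimated as well.
#'
#' @param data Baseline-corrected long-format data frame (responders from
#'   stress conditions).
#' @param b0 Fixed baseline; defaults to the mean cortisol at `t = 0`.
#' @param extended Estimate `dT` and `b1` in addition to `alpha`, `beta`,
#'   `A` (default `FALSE`, the selected four-parameter model).
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return Object of class `population_curve`: the fitted
#'   [response_curve()], per-participant mean absolute error and bias, and
#'   fit statistics (`rss`, `sigma`, `logLik`, `bic`, `n_obs`).
#' @export
fit_population_curve <- function(data, b0 = NULL, extended = FALSE,
                                 control = minpack.lm::nls.lm.control(maxiter = 200)) {
  check_long_data(data)
  t <- data$time_min
  y <- data$cortisol_nmol_l
  if (is.null(b0)) {
    at0 <- t == 0
    if (!any(at0)) stop("no baseline samples at t = 0 to fix b0", call. = FALSE)
    b0 <- mean(y[at0])
  }
  st <- pop_start_values(t, y, b0)
  resid_fun <- if (extended) {
    function(p) {
      x <- t - p["dT"]
      y - (p["A"] * gamma_density(x, exp(p["lalpha"]), exp(p["lbeta"])) +
             b0 + p["b1"] * x)
    }
  } else {
    function(p) {
      y - (p["A"] * gamma_density(t, exp(p["lalpha"]), exp(p["lbeta"])) + b0)
    }
  }
  start <- unlist(st)
  if (extended) start <- c(start, dT = 0, b1 = 0)
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun, control = control)
  if (!(fit$info %in% 1:4)) {
    stop("population curve fit did not converge (info = ", fit$info,
         ", residual = ", format(fit$deviance), ")", call. = FALSE)
  }
  p <- fit$par
  curve <- response_curve(alpha = exp(p[["lalpha"]]), beta = exp(p[["lbeta"]]),
                          A = p[["A"]], b0 = b0,
                          b1 = if (extended) p[["b1"]] else 0,
                          dT = if (extended) p[["dT"]] else 0)
  pred <- eval_curve(curve, t)
  n <- length(y)
  rss <- sum((y - pred)^2)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- length(start) + 1 # + residual SD
  diag_df <- data.frame(
    participant_id = as.character(data$participant_id),
    err = y - pred
  )
  per <- do.call(rbind, lapply(split(diag_df$err, diag_df$participant_id),
                               function(e) c(mae = mean(abs(e)), bias = mean(e))))
  structure(list(
    curve = curve, b0_pop = b0, extended = extended,
    rss = rss, sigma = sqrt(sigma2), logLik = ll,
    bic = k * log(n) - 2 * ll, n_obs = n,
    n_participants = length(unique(data$participant_id)),
    diagnostics = data.frame(participant_id = rownames(per),
                             mae = per[, "mae"], bias = per[, "bias"],
                             row.names = NULL)
  ), class = "population_curve")
}

#' @export
print.population_curve <- function(x, ...) {
  cat("Population-average cortisol response curve",
      if (x$extended) "(extended: dT, b1)" else "(4-parameter)", "\n")
  print(x$curve)
  cat(sprintf("  fitted on %d samples from %d participants; sigma = %.3f nmol/L, BIC = %.1f\n",
              x$n_obs, x$n_participants, x$sigma, x$bic))
  invisible(x)
}

#' @export
coef.population_curve <- function(object, ...) {
  with(object$curve, c(alpha = alpha, beta = beta, A = A, b0 = b0, b1 = b1, dT = dT))
}

#' @export
predict.population_curve <- function(object, times = time_grid(0, 80), ...) {
  eval_curve(object$curve, times)
}

#' Choose between the four-parameter and extended population curve
#'
#' Fits both the four-parameter model (`alpha`, `beta`, `A`, fixed `b0`)
#' and the extended model with `dT` and `b1`, and selects the fit with the
#' lower Bayesian Information Criterion; on a tie (within 1e-9) the simpler
#' model wins.
#'
#' @inheritParams fit_population_curve
#' @return List with `chosen` (`"basic"` or `"extended"`), `bic_basic`,
#'   `bic_extended`, and both fits.
#' @export
select_population_model <- function(data, b0 = NULL) {
  basic <- fit_population_curve(data, b0 = b0, extended = FALSE)
  ext <- fit_population_curve(data, b0 = b0, extended = TRUE)
  chosen <- if (ext$bic < basic$bic - 1e-9) "extended" else "basic"
  list(chosen = chosen, bic_basic = basic$bic, bic_extended = ext$bic,
       basic = basic, extended = ext)
}

#' Re-estimate the response amplitude for one individual
#'
#' Three-step amplitude scaling: (1) observations are normalized by
#' subtracting the individual's observed baseline at `t = 0`; (2) the
#' normalized post-baseline data are regressed on the unit-amplitude
#' population shape, giving the closed-form least-squares amplitude
#' `A_i = sum(y_j * f(t_j)) / sum(f(t_j)^2)`; (3) the individual's curve is
#' the population shape with amplitude `A_i` shifted by the observed
#' baseline. `A_i` is unconstrained in sign, so declining (control or
#' non-responder) profiles map to amplitudes near or below zero.
#'
#' @param time,cortisol One baseline-corrected series (baseline at `t = 0`
#'   present, at least one post-baseline sample).
#' @param pop A `population_curve` from [fit_population_curve()].
#' @return List with `A`, `baseline`, and the individual's
#'   [response_curve()].
#' @export
fit_individual_amplitude <- function(time, cortisol, pop) {
  stopifnot(inherits(pop, "population_curve"))
  ib <- which(time == 0)
  if (length(ib) != 1) stop("series must have exactly one baseline at t = 0", call. = FALSE)
  base <- cortisol[ib]
  post <- time > 0
  if (!any(post)) stop("no post-baseline sample", call. = FALSE)
  f <- gamma_density(time[post], pop$curve$alpha, pop$curve$beta)
  denom <- sum(f^2)
  if (denom == 0) stop("population shape is zero at all sampled times", call. = FALSE)
  A <- sum((cortisol[post] - base) * f) / denom
  list(A = A, baseline = base,
       curve = response_curve(pop$curve$alpha, pop$curve$beta, A = A, b0 = base))
}

#' Fit the amplitude scaling model
#'
#' Full pipeline: classify stress-condition responders, fit the
#' population-average curve on their pooled samples (baseline fixed to the
#' sample mean at `t = 0`), then re-estimate the amplitude for every series
#' in the data (including controls and non-responders).
#'
#' @param data Baseline-corrected long-format data frame.
#' @param pop Optionally a pre-fitted `population_curve` (e.g. read with
#'   [read_population_curve()]); when supplied, only amplitudes are fitted.
#' @param responder_threshold,responder_window Passed to
#'   [classify_responders()].
#' @param extended Passed to [fit_population_curve()].
#' @return Object of class `asm_fit` with the population curve and a
#'   per-series amplitude table (`participant_id`, `condition`, `A`,
#'   `baseline`, `n_obs`, `mae`, `bias`).
#' @seealso [indicators_model()] to derive summary indicators.
#' @export
fit_asm <- function(data, pop = NULL, responder_threshold = 1.5,
                    responder_window = c(15, 45), extended = FALSE) {
  check_long_data(data)
  cl <- match.call()
  if (is.null(pop)) {
    resp <- classify_responders(data, responder_threshold, responder_window)
    keep <- resp[!is.na(resp$responder) & resp$responder, , drop = FALSE]
    if ("condition" %in% names(data)) {
      keep <- keep[is.na(keep$condition) | keep$condition != "control", , drop = FALSE]
    }
    key <- if ("condition" %in% names(data)) {
      paste(data$participant_id, data$condition, sep = "\r")
    } else as.character(data$participant_id)
    keep_key <- paste(keep$participant_id,
                      if ("condition" %in% names(keep)) keep$condition else NA,
                      sep = "\r")
    if (!"condition" %in% names(data)) keep_key <- as.character(keep$participant_id)
    fit_data <- data[key %in% keep_key, , drop = FALSE]
    if (nrow(fit_data) == 0) stop("no stress-condition responders to fit the population curve",
                                  call. = FALSE)
    pop <- fit_population_curve(fit_data, extended = extended)
  }
  pieces <- split_series(data)
  rows <- lapply(pieces, function(s) {
    s <- s[order(s$time_min), , drop = FALSE]
    m <- series_meta(s)
    fit <- tryCatch(fit_individual_amplitude(s$time_min, s$cortisol_nmol_l, pop),
                    error = function(e) NULL)
    if (is.null(fit)) {
      m$A <- NA_real_; m$baseline <- NA_real_; m$n_obs <- nrow(s)
      m$mae <- NA_real_; m$bias <- NA_real_
      return(m)
    }
    pred <- eval_curve(fit$curve, s$time_min)
    m$A <- fit$A; m$baseline <- fit$baseline; m$n_obs <- nrow(s)
    m$mae <- mean(abs(s$cortisol_nmol_l - pred))
    m$bias <- mean(s$cortisol_nmol_l - pred)
    m
  })
  amplitudes <- do.call(rbind, rows)
  rownames(amplitudes) <- NULL
  structure(list(population = pop, amplitudes = amplitudes, call = cl),
            class = "asm_fit")
}

asm_curve <- function(object, i) {
  a <- object$amplitudes
  response_curve(object$population$curve$alpha, object$population$curve$beta,
                 A = a$A[i], b0 = a$baseline[i])
}

#' @export
print.asm_fit <- function(x, ...) {
  cat("Amplitude scaling model\n")
  print(x$population)
  a <- x$amplitudes
  cat(sprintf("  %d individual series; amplitude A: median %.1f [IQR %.1f, %.1f]\n",
              nrow(a), stats::median(a$A, na.rm = TRUE),
              stats::quantile(a$A, 0.25, na.rm = TRUE),
              stats::quantile(a$A, 0.75, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.asm_fit <- function(object, ...) {
  a <- object$amplitudes
  out <- list(population = coef(object$population),
              n_series = nrow(a),
              amplitude = summary(a$A),
              mae = mean(a$mae, na.rm = TRUE),
              bias = mean(a$bias, na.rm = TRUE))
  class(out) <- "summary.asm_fit"
  out
}

#' @export
print.summary.asm_fit <- function(x, ...) {
  cat("Amplitude scaling model summary\n  population parameters:\n")
  print(round(x$population, 4))
  cat(sprintf("  %d series; mean per-series MAE %.3f, bias %.3f nmol/L\n",
              x$n_series, x$mae, x$bias))
  cat("  amplitude distribution:\n")
  print(x$amplitude)
  invisible(x)
}

#' @export
coef.asm_fit <- function(object, ...) coef(object$population)

#' Predict individual cortisol values from an amplitude scaling fit
#'
#' @param object An `asm_fit`.
#' @param participant_id Series to predict (with `condition` when the data
#'   had one); defaults to all.
#' @param times Times in minutes.
#' @param ... Unused.
#' @return Matrix of predictions, one row per requested series.
#' @export
predict.asm_fit <- function(object, participant_id = NULL,
                            times = time_grid(0, 80), condition = NULL, ...) {
  a <- object$amplitudes
  idx <- seq_len(nrow(a))
  if (!is.null(participant_id)) {
    idx <- idx[a$participant_id %in% as.character(participant_id)]
    if (!is.null(condition)) idx <- idx[a$condition[idx] %in% condition]
    if (length(idx) == 0) stop("unknown participant_id", call. = FALSE)
  }
  res <- vapply(idx, function(i) eval_curve(asm_curve(object, i), times),
                numeric(length(times)))
  out <- if (length(times) == 1) matrix(res, ncol = 1) else t(res)
  rownames(out) <- a$participant_id[idx]
  colnames(out) <- times
  out
}

#' @export
residuals.asm_fit <- function(object, ...) {
  object$amplitudes$bias
}

#' @export
plot.asm_fit <- function(x, window = c(0, 80), ...) {
  plot(x$population$curve, window = window,
       main = "Population-average cortisol response", ...)
  invisible(x)
}

#' Serialize a population curve to JSON
#'
#' Writes the fitted population-average curve (alpha, beta, A, b0 and
#' provenance metadata) so the amplitude scaling model can be applied to
#' new datasets without refitting.
#'
#' @param pop A `population_curve`.
#' @param path Output file path (`.json`).
#' @export
write_population_curve <- function(pop, path) {
  stopifnot(inherits(pop, "population_curve"))
  doc <- list(
    model = "gamma-kernel population average cortisol response",
    parameters = as.list(coef(pop)),
    fit = list(n_obs = pop$n_obs, n_participants = pop$n_participants,
               sigma = pop$sigma, bic = pop$bic),
    provenance = list(package = "cortcurve",
                      version = as.character(utils::packageVersion("cortcurve")),
                      date = format(Sys.Date()))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized population curve
#'
#' @param path Path written by [write_population_curve()].
#' @return A `population_curve` object (without per-participant
#'   diagnostics).
#' @export
read_population_curve <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- doc$parameters
  structure(list(
    curve = response_curve(p$alpha, p$beta, A = p$A, b0 = p$b0,
                           b1 = if (is.null(p$b1)) 0 else p$b1,
                           dT = if (is.null(p$dT)) 0 else p$dT),
    b0_pop = p$b0, extended = !is.null(p$dT) && (p$dT != 0 || p$b1 != 0),
    rss = NA_real_, sigma = doc$fit$sigma, logLik = NA_real_,
    bic = doc$fit$bic, n_obs = doc$fit$n_obs,
    n_participants = doc$fit$n_participants,
    diagnostics = NULL
  ), class = "population_curve")
}
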
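# Observation-based and model-based summary indicators of the cortisol
# stress response: AUCg, AUCi, reactivity, maximum increase.

#' Observation-based area under the cortisol curve
#'
#' Trapezoidal AUC over the sampled timepoints. With respect to ground
#' (`"ground"`, AUCg) the raw curve is integrated; with respect to
#' increase (`"increase"`, AUCi) the area of the first sample's rectangle
#' is subtracted: `AUCi = AUCg - c_first * (t_last - t_first)`.
#'
#' @param time,cortisol Numeric vectors of one time-ordered series
#'   (at least two samples).
#' @param type `"ground"` or `"increase"`.
#' @return Area in nmol/L * min.
#' @examples
#' auc_obs(c(0, 15, 30, 45), c(5, 9, 7, 6))                 # AUCg 322.5
#' auc_obs(c(0, 15, 30, 45), c(5, 9, 7, 6), "increase")     # AUCi 97.5
#' @export
auc_obs <- function(time, cortisol, type = c("ground", "increase")) {
  type <- match.arg(type)
  if (length(time) < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    o <- order(time)
    time <- time[o]; cortisol <- cortisol[o]
  }
  n <- length(time)
  aucg <- sum((cortisol[-n] + cortisol[-1]) / 2 * diff(time))
  if (type == "ground") aucg else aucg - cortisol[1] * (time[n] - time[1])
}

#' Observation-based reactivity
#'
#' Cortisol at the sample nearest to the expected peak time minus the
#' baseline value at `t = 0`. When two samples are equally close the
#' earlier one is used; set `interpolate = TRUE` to linearly interpolate
#' between the two nearest samples instead.
#'
#' @param time,cortisol One baseline-corrected series.
#' @param peak_time Expected peak in minutes post-onset (default 25, the
#'   midpoint of the 15-45 min responder window).
#' @param interpolate Linearly interpolate at `peak_time` instead of
#'   taking the nearest sample.
#' @return Reactivity in nmol/L (may be negative for declining profiles).
#' @export
reactivity_obs <- function(time, cortisol, peak_time = 25, interpolate = FALSE) {
  ib <- which(time == 0)
  if (length(ib) != 1) stop("series must have exactly one baseline at t = 0", call. = FALSE)
  post <- which(time > 0)
  if (length(post) == 0) stop("no post-baseline sample", call. = FALSE)
  base <- cortisol[ib]
  if (interpolate) {
    v <- stats::approx(time, cortisol, xout = peak_time, rule = 2)$y
    return(v - base)
  }
  d <- abs(time[post] - peak_time)
  # earliest among nearest (ties broken to earlier time)
  cand <- post[d == min(d)]
  cortisol[cand[which.min(time[cand])]] - base
}

#' Observation-based maximum increase
#'
#' Largest excursion of cortisol above the baseline across all samples
#' (baseline included), hence non-negative by definition: a monotone
#' decline yields 0.
#'
#' @param time,cortisol One baseline-corrected series.
#' @return Maximum increase in nmol/L, `>= 0`.
#' @export
max_increase_obs <- function(time, cortisol) {
  ib <- which(time == 0)
  if (length(ib) != 1) stop("series must have exactly one baseline at t = 0", call. = FALSE)
  max(cortisol) - cortisol[ib]
}

#' Observation-based indicator table for a dataset
#'
#' @param data Baseline-corrected long-format data frame.
#' @param peak_time Expected peak used for reactivity (minutes).
#' @param interpolate Passed to [reactivity_obs()].
#' @param method_label Label stored in the `method` column (default
#'   `"OBS"`).
#' @param use_nominal_times Use the `nominal_time` column (schedule-mean
#'   timings) instead of actual times when present, mirroring conventional
#'   analyses that ignore individual timing variation.
#' @return Data frame with one row per series: `participant_id`,
#'   `condition`, `method`, `AUCg`, `AUCi`, `reactivity`, `max_increase`.
#' @export
indicators_obs <- function(data, peak_time = 25, interpolate = FALSE,
                           method_label = "OBS", use_nominal_times = FALSE) {
  check_long_data(data)
  pieces <- split_series(data)
  out <- lapply(pieces, function(s) {
    s <- s[order(s$time_min), , drop = FALSE]
    tm <- if (use_nominal_times && "nominal_time" %in% names(s)) s$nominal_time else s$time_min
    m <- series_meta(s)
    m$method <- method_label
    m$AUCg <- tryCatch(auc_obs(tm, s$cortisol_nmol_l), error = function(e) NA_real_)
    m$AUCi <- tryCatch(auc_obs(tm, s$cortisol_nmol_l, "increase"),
                       error = function(e) NA_real_)
    m$reactivity <- tryCatch(
      reactivity_obs(tm, s$cortisol_nmol_l, peak_time, interpolate),
      error = function(e) NA_real_)
    m$max_increase <- tryCatch(max_increase_obs(tm, s$cortisol_nmol_l),
                               error = function(e) NA_real_)
    m
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

model_indicator_row <- function(curve, window, step, peak_time) {
  grid <- time_grid(window[1], window[2], step)
  vals <- eval_curve(curve, grid)
  c0 <- vals[1]
  n <- length(grid)
  aucg <- sum((vals[-n] + vals[-1]) / 2 * diff(grid))
  auci <- aucg - c0 * (window[2] - window[1])
  if (is.null(peak_time)) {
    if (curve$A == 0 && curve$b1 == 0) {
      react <- 0
    } else {
      pk <- curve_peak(curve, window = window)
      react <- pk$value - c0
    }
  } else {
    react <- eval_curve(curve, peak_time) - c0
  }
  maxinc <- max(0, max(vals) - c0)
  c(AUCg = aucg, AUCi = auci, reactivity = react, max_increase = maxinc)
}

#' Model-based summary indicators
#'
#' Computes AUCg, AUCi, reactivity and maximum increase from fitted
#' response curves evaluated on a regular grid over the indicator window
#' (default 1-min steps over 0-80 min), so the indicators are independent
#' of which samples produced the fit. The curve's own value at `t = 0`
#' serves as baseline.
#'
#' For an `asm_fit`, reactivity is evaluated at the population curve's
#' peak time for every individual, making ASM reactivity exactly
#' proportional to the individual amplitude (and therefore perfectly rank-
#' correlated with ASM AUCi). For an `mlm_fit` or a bare `response_curve`,
#' reactivity uses each curve's own peak location; flat curves yield
#' reactivity and maximum increase of 0.
#'
#' @param object A [response_curve()], `asm_fit` or `mlm_fit`.
#' @param window Indicator window in minutes, default `c(0, 80)`.
#' @param step Evaluation grid step in minutes, default 1.
#' @param peak_time Optional fixed peak time (minutes) overriding the
#'   per-curve peak search.
#' @param ... Unused.
#' @return For a single curve, a named numeric vector; for fitted models a
#'   data frame with one row per series plus a `method` column (`"ASM"` or
#'   `"MM"`).
#' @export
indicators_model <- function(object, ...) UseMethod("indicators_model")

#' @rdname indicators_model
#' @export
indicators_model.response_curve <- function(object, window = c(0, 80), step = 1,
                                            peak_time = NULL, ...) {
  model_indicator_row(object, window, step, peak_time)
}

#' @rdname indicators_model
#' @export
indicators_model.asm_fit <- function(object, window = c(0, 80), step = 1, ...) {
  pop_peak <- curve_peak(
    response_curve(object$population$curve$alpha, object$population$curve$beta,
                   A = abs(object$population$curve$A), b0 = 0),
    window = window)$t_peak
  a <- object$amplitudes
  rows <- t(vapply(seq_len(nrow(a)), function(i) {
    if (is.na(a$A[i])) return(c(AUCg = NA_real_, AUCi = NA_real_,
                                reactivity = NA_real_, max_increase = NA_real_))
    model_indicator_row(asm_curve(object, i), window, step, peak_time = pop_peak)
  }, numeric(4)))
  out <- data.frame(participant_id = a$participant_id, condition = a$condition,
                    method = "ASM", rows, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname indicators_model
#' @export
indicators_model.mlm_fit <- function(object, window = c(0, 80), step = 1,
                                     peak_time = NULL, ...) {
  p <- object$psi
  rows <- t(vapply(seq_len(nrow(p)), function(i) {
    crv <- response_curve(p$alpha[i], p$beta[i], A = p$A[i], b0 = p$b0[i],
                          b1 = p$b1[i], dT = p$dT[i])
    model_indicator_row(crv, window, step, peak_time)
  }, numeric(4)))
  out <- data.frame(participant_id = p$participant_id,
                    condition = if ("condition" %in% names(p)) p$condition else NA_character_,
                    method = "MM", rows, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' "True" indicators from high-resolution simulated trajectories
#'
#' Computes the four indicators from each individual's red-noise
#' trajectory (structural curve plus synthesis noise, free of measurement
#' noise) on the full 1-min grid over the indicator window, serving as
#' ground truth for accuracy evaluation. AUCs integrate the trajectory by
#' the trapezoidal rule; maximum increase is the largest excursion above
#' the trajectory's value at `t = 0`; reactivity is evaluated at the
#' individual's structural peak time (`peak = "structural"`, default) or
#' at the trajectory's own argmax (`peak = "argmax"`, in which case it
#' coincides with maximum increase).
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param window Indicator window, default `c(0, 80)`; the simulation grid
#'   must cover it.
#' @param peak `"structural"` or `"argmax"`.
#' @return Data frame with one row per individual, `method = "TRUE"`.
#' @export
true_indicators <- function(cohort, window = c(0, 80),
                            peak = c("structural", "argmax")) {
  stopifnot(inherits(cohort, "sim_cohort"))
  peak <- match.arg(peak)
  times <- cohort$times
  if (min(times) > window[1] || max(times) < window[2]) {
    stop("simulation grid does not cover the indicator window", call. = FALSE)
  }
  keep <- times >= window[1] & times <= window[2]
  tt <- times[keep]
  X <- cohort$red[, keep, drop = FALSE]
  n <- ncol(X)
  w <- diff(tt)
  aucg <- as.numeric((X[, -n, drop = FALSE] + X[, -1, drop = FALSE]) %*% w / 2)
  c0 <- X[, 1]
  auci <- aucg - c0 * (window[2] - window[1])
  maxinc <- pmax(0, apply(X, 1, max) - c0)
  react <- if (peak == "argmax") {
    apply(X, 1, max) - c0
  } else {
    pk_t <- with(cohort$params, pmin(pmax((alpha - 1) / beta + dT, window[1]), window[2]))
    idx <- vapply(pk_t, function(p) which.min(abs(tt - p)), integer(1))
    X[cbind(seq_len(nrow(X)), idx)] - c0
  }
  data.frame(participant_id = cohort$params$participant_id,
             condition = "stress", method = "TRUE",
             AUCg = aucg, AUCi = auci, reactivity = react,
             max_increase = maxinc, stringsAsFactors = FALSE)
}

#' Indicator table for a dataset under a chosen method
#'
#' Convenience driver used in schedule-robustness evaluations: computes
#' the indicator table for long-format data using the conventional
#' observation-based method (`"obs"`), the amplitude scaling model
#' (`"asm"`) or the multilevel model (`"mm"`).
#'
#' @param data Baseline-corrected long-format data frame.
#' @param method One of `"obs"`, `"asm"`, `"mm"`.
#' @param peak_time Expected peak time for observation-based reactivity.
#' @param pop Optional pre-fitted `population_curve` for `"asm"`.
#' @param spec Optional [mlm_spec()] for `"mm"`.
#' @param ... Passed to the underlying fitter.
#' @return Tidy indicator data frame (`participant_id`, `condition`,
#'   `method`, `AUCg`, `AUCi`, `reactivity`, `max_increase`).
#' @export
indicator_table <- function(data, method = c("obs", "asm", "mm"),
                            peak_time = 25, pop = NULL, spec = mlm_spec(), ...) {
  method <- match.arg(method)
  switch(method,
    obs = indicators_obs(data, peak_time = peak_time, ...),
    asm = indicators_model(fit_asm(data, pop = pop, ...)),
    mm = indicators_model(fit_mlm(data, spec = spec, ...))
  )
}
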
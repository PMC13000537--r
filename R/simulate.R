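# Stochastic cohort simulator: structural gamma-kernel response per
# virtual individual, red synthesis noise as a zero-mean Ornstein-Uhlenbeck
# deviation around the structural curve (Euler-Maruyama integration on a
# 1-min grid), plus additive white measurement noise. Downsampling to arbitrary
# sampling schedules mimics real acute stress test studies.

#' Configuration of the stochastic cohort simulator
#'
#' Population distributions were chosen so the population-average response
#' resembles a TSST cohort: the gamma kernel peaks 19-25 min post onset,
#' the median responder's peak increase is about 6 nmol/L above a baseline
#' near 5.5 nmol/L, and red plus white noise each contribute about
#' 1 nmol/L of spread. Parameter draws are independent log-normals for
#' `alpha`, `beta`, `A` and a truncated normal for `b0`; a configurable
#' fraction of non-responders receives a near-zero (possibly negative)
#' amplitude so declining profiles occur.
#'
#' @param n Number of virtual individuals (default 500 for desk use;
#'   increase for production runs).
#' @param female_fraction Fraction of females, default 0.5.
#' @param t_start,t_stop,dt Simulation grid in minutes relative to
#'   stressor onset; the default -20 to 80 min in 1-min steps lets red
#'   noise approach stationarity before `t = 0`.
#' @param alpha_meanlog,alpha_sdlog,beta_meanlog,beta_sdlog Log-normal
#'   parameters of the gamma kernel shape and rate.
#' @param A_meanlog,A_sdlog Log-normal amplitude distribution of
#'   responders (nmol/L * min).
#' @param b0_mean,b0_sd,b0_min Baseline distribution (normal, truncated
#'   below at `b0_min` nmol/L).
#' @param male_A_factor Multiplicative male amplitude effect.
#' @param male_b0_shift Additive male baseline shift (nmol/L).
#' @param nonresponder_fraction Fraction of individuals with no structural
#'   response; their amplitude is drawn `N(0, nonresponder_A_sd)`.
#' @param nonresponder_A_sd SD of non-responder amplitudes.
#' @param sigma_white White measurement-noise SD (nmol/L).
#' @param theta_red Mean-reversion rate of the red-noise process (1/min).
#' @param sigma_red Diffusion scale of the red-noise process
#'   (nmol/L / sqrt(min)); the stationary red-noise SD is
#'   `sigma_red / sqrt(2 * theta_red)`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n = 500, female_fraction = 0.5,
                       t_start = -20, t_stop = 80, dt = 1,
                       alpha_meanlog = log(3.2), alpha_sdlog = 0.18,
                       beta_meanlog = log(0.115), beta_sdlog = 0.18,
                       A_meanlog = log(200), A_sdlog = 0.7,
                       b0_mean = 5.5, b0_sd = 1.3, b0_min = 0.5,
                       male_A_factor = 1.2, male_b0_shift = 0.5,
                       nonresponder_fraction = 0.2, nonresponder_A_sd = 10,
                       sigma_white = 1, theta_red = 0.1, sigma_red = 0.45,
                       seed = 1) {
  cfg <- as.list(environment())
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (sigma_white < 0 || sigma_red < 0) stop("noise SDs must be >= 0", call. = FALSE)
  if (sigma_red > 0 && theta_red <= 0) {
    stop("`theta_red` must be > 0 when `sigma_red` > 0", call. = FALSE)
  }
  if (female_fraction < 0 || female_fraction > 1) {
    stop("`female_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a cohort of cortisol stress-response trajectories
#'
#' For each virtual individual: curve parameters are drawn from the
#' population distributions in `config`; the red-noise trajectory is
#' `X(t) = g(t) + R(t)` where the synthesis-noise deviation follows the
#' Ornstein-Uhlenbeck equation `dR = -theta_red R dt + sigma_red dW`,
#' integrated by the Euler-Maruyama method from `R(t_start) = 0`; the
#' observed trajectory adds i.i.d. `N(0, sigma_white^2)` measurement
#' noise. With both noise scales zero the trajectories equal the
#' deterministic structural curve. Everything is reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_cohort`: `params` (per-individual true
#'   curve parameters and gender), `times` (simulation grid), `red` and
#'   `obs` (n x length(times) trajectory matrices), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n
    gender <- sample(rep(c("F", "M"),
                         times = c(round(n * config$female_fraction),
                                   n - round(n * config$female_fraction))))
    alpha <- rlnorm(n, config$alpha_meanlog, config$alpha_sdlog)
    beta <- rlnorm(n, config$beta_meanlog, config$beta_sdlog)
    A <- rlnorm(n, config$A_meanlog, config$A_sdlog)
    A[gender == "M"] <- A[gender == "M"] * config$male_A_factor
    nr <- runif(n) < config$nonresponder_fraction
    A[nr] <- rnorm(sum(nr), 0, config$nonresponder_A_sd)
    b0 <- pmax(rnorm(n, config$b0_mean, config$b0_sd), config$b0_min)
    b0[gender == "M"] <- b0[gender == "M"] + config$male_b0_shift
    times <- time_grid(config$t_start, config$t_stop, config$dt)
    nt <- length(times)
    # structural curves, n x nt (dgamma vectorizes over individuals)
    G <- sapply(times, function(tj) {
      x <- rep(tj, n)
      f <- numeric(n)
      pos <- x > 0
      f[pos] <- stats::dgamma(x[pos], shape = alpha[pos], rate = beta[pos])
      A * f + b0
    })
    if (!is.matrix(G)) G <- matrix(G, nrow = n)
    # red synthesis noise: zero-mean OU deviation R around the structural
    # curve, dR = -theta R dt + sigma dW, integrated by Euler-Maruyama from
    # R(t_start) = 0 (the -20 min burn-in approaches stationarity by t = 0)
    R <- matrix(0, n, nt)
    if (nt > 1 && config$sigma_red > 0) {
      sw <- config$sigma_red * sqrt(config$dt)
      for (j in 2:nt) {
        R[, j] <- R[, j - 1] - config$theta_red * R[, j - 1] * config$dt +
          sw * rnorm(n)
      }
    }
    X <- G + R
    obs <- X + matrix(rnorm(n * nt, 0, config$sigma_white), n, nt)
    params <- data.frame(participant_id = sprintf("sim%05d", seq_len(n)),
                         gender = gender, alpha = alpha, beta = beta, A = A,
                         b0 = b0, b1 = 0, dT = 0, responder_draw = !nr,
                         stringsAsFactors = FALSE)
    structure(list(params = params, times = times, red = X, obs = obs,
                   config = config),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cortisol cohort: %d individuals, grid %g..%g min (dt = %g)\n",
              nrow(x$params), min(x$times), max(x$times), x$config$dt))
  cat(sprintf("  noise: white SD %.2f, red theta %.3f /min sigma %.3f (stationary SD %.2f)\n",
              x$config$sigma_white, x$config$theta_red, x$config$sigma_red,
              if (x$config$theta_red > 0) x$config$sigma_red / sqrt(2 * x$config$theta_red) else 0))
  invisible(x)
}

#' @export
`[.sim_cohort` <- function(x, i, ...) {
  structure(list(params = x$params[i, , drop = FALSE], times = x$times,
                 red = x$red[i, , drop = FALSE], obs = x$obs[i, , drop = FALSE],
                 config = x$config),
            class = "sim_cohort")
}

#' Define a sampling schedule
#'
#' @param times Ordered measurement timepoints in minutes; the first must
#'   be the baseline 0 and all must lie in `[0, 80]`.
#' @param id Schedule label (default derived from the timepoints).
#' @param min_duration Minimum allowed last timepoint (default 30 min).
#' @return Object of class `sampling_schedule` with fields `id`, `times`
#'   and `duration`.
#' @export
sampling_schedule <- function(times, id = NULL, min_duration = 30) {
  if (length(times) < 2) stop("a schedule needs at least 2 timepoints", call. = FALSE)
  if (times[1] != 0) stop("first timepoint must be the baseline 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) stop("timepoints must be strictly increasing", call. = FALSE)
  if (any(times < 0 | times > 80)) stop("timepoints must lie in [0, 80]", call. = FALSE)
  duration <- times[length(times)]
  if (duration < min_duration) {
    stop("schedule duration ", duration, " min is below the minimum ",
         min_duration, " min", call. = FALSE)
  }
  if (is.null(id)) id <- paste0("s", paste(times, collapse = "-"))
  structure(list(id = id, times = times, duration = duration),
            class = "sampling_schedule")
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat(sprintf("Sampling schedule %s: [%s] (%g min)\n", x$id,
              paste(x$times, collapse = ", "), x$duration))
  invisible(x)
}

#' Group sampling schedules that vary one design factor
#'
#' @param factor One of `"duration"`, `"frequency"`, `"peak_timepoint"`,
#'   `"representative"`, `"high_variability"`.
#' @param schedules List of [sampling_schedule()] objects.
#' @return Object of class `schedule_set`.
#' @export
schedule_set <- function(factor, schedules) {
  factor <- match.arg(factor, c("duration", "frequency", "peak_timepoint",
                                "representative", "high_variability"))
  stopifnot(all(vapply(schedules, inherits, logical(1), "sampling_schedule")))
  names(schedules) <- vapply(schedules, `[[`, character(1), "id")
  structure(list(factor = factor, schedules = schedules), class = "schedule_set")
}

#' Built-in schedule sets for robustness evaluation
#'
#' Documented default sets, each varying a single design factor:
#'
#' * `duration`: shared early timepoints, last sample at 40, 60 or 80 min;
#' * `frequency`: 3, 5 or 9 equally spaced samples over the full 0-80 min
#'   span;
#' * `peak_recovery`: peak sample at 15, 25 or 35 min with late recovery
#'   samples;
#' * `peak_no_recovery`: peak sample at 15, 25 or 35 min, sampling
#'   discontinued at 40 min;
#' * `representative`: twelve schedules spanning realistic study designs
#'   (3-9 samples, 40-80 min durations);
#' * `high_variability`: five widely differing schedules including the
#'   very sparse `[0, 30]` design.
#'
#' @return Named list of [schedule_set()] objects.
#' @export
default_schedule_sets <- function() {
  sch <- function(...) sampling_schedule(c(...))
  list(
    duration = schedule_set("duration", list(
      sch(0, 15, 25, 40),
      sch(0, 15, 25, 40, 60),
      sch(0, 15, 25, 40, 60, 80))),
    frequency = schedule_set("frequency", list(
      sch(0, 40, 80),
      sch(0, 20, 40, 60, 80),
      sch(0, 10, 20, 30, 40, 50, 60, 70, 80))),
    peak_recovery = schedule_set("peak_timepoint", list(
      sch(0, 15, 60, 80),
      sch(0, 25, 60, 80),
      sch(0, 35, 60, 80))),
    peak_no_recovery = schedule_set("peak_timepoint", list(
      sch(0, 15, 40),
      sch(0, 25, 40),
      sch(0, 35, 40))),
    representative = schedule_set("representative", list(
      sch(0, 15, 25, 35, 45, 60, 80),
      sch(0, 10, 20, 30, 40),
      sch(0, 20, 40, 60),
      sch(0, 15, 30, 45, 60),
      sch(0, 25, 50, 80),
      sch(0, 10, 25, 40, 55, 70),
      sch(0, 30, 60),
      sch(0, 15, 35, 55, 75),
      sch(0, 20, 45, 70),
      sch(0, 10, 20, 40, 80),
      sch(0, 15, 45, 80),
      sch(0, 5, 15, 25, 35, 45, 55, 65, 75))),
    high_variability = schedule_set("high_variability", list(
      sampling_schedule(c(0, 30), min_duration = 30),
      sch(0, 10, 20, 30, 40, 50, 60, 70, 80),
      sch(0, 40, 80),
      sch(0, 15, 25, 35, 45, 60),
      sch(0, 20, 60, 80)))
  )
}

#' Downsample a simulated cohort to a sampling schedule
#'
#' Extracts the observed-trajectory values (red noise plus measurement
#' noise) at exactly the schedule's timepoints and returns them in the
#' long data format shared with real data. Timepoints must lie on the
#' simulation grid (1-min precision by default); tiny negative cortisol
#' values that white noise can produce are truncated at 0.
#'
#' @param cohort A `sim_cohort`.
#' @param schedule A [sampling_schedule()].
#' @return Long-format data frame (`participant_id`, `study_id` = the
#'   schedule id, `condition`, `gender`, `age`, `test_type`, `time_min`,
#'   `cortisol_nmol_l`).
#' @export
downsample <- function(cohort, schedule) {
  stopifnot(inherits(cohort, "sim_cohort"), inherits(schedule, "sampling_schedule"))
  idx <- match_times(schedule$times, cohort$times)
  n <- nrow(cohort$params)
  k <- length(idx)
  data.frame(
    participant_id = rep(cohort$params$participant_id, each = k),
    study_id = schedule$id,
    condition = "stress",
    gender = rep(cohort$params$gender, each = k),
    age = NA_real_,
    test_type = "TSST",
    time_min = rep(schedule$times, times = n),
    cortisol_nmol_l = pmax(as.numeric(t(cohort$obs[, idx, drop = FALSE])), 0),
    stringsAsFactors = FALSE
  )
}

match_times <- function(wanted, grid) {
  vapply(wanted, function(w) {
    j <- which(abs(grid - w) < 1e-9)
    if (length(j) != 1) {
      stop("timepoint ", w, " min is not on the simulation grid", call. = FALSE)
    }
    j
  }, integer(1))
}

#' Build a combined dataset by random schedule allocation
#'
#' Each simulated participant is uniformly allocated one schedule from the
#' set; the resulting long-format data mimics a combined database of
#' studies with heterogeneous sampling schedules. Repeat with different
#' seeds to obtain replicate combined datasets.
#'
#' @param cohort A `sim_cohort`.
#' @param set A [schedule_set()].
#' @param seed Integer seed for the allocation.
#' @return List with `data` (long format), `allocation` (data frame
#'   `participant_id`, `schedule_id`, `duration`), and `set`.
#' @export
build_combined_dataset <- function(cohort, set, seed = 1) {
  stopifnot(inherits(cohort, "sim_cohort"), inherits(set, "schedule_set"))
  k <- length(set$schedules)
  n <- nrow(cohort$params)
  alloc <- with_seed(seed, sample.int(k, n, replace = TRUE))
  parts <- lapply(seq_len(k), function(j) {
    sel <- which(alloc == j)
    if (length(sel) == 0) return(NULL)
    downsample(cohort[sel], set$schedules[[j]])
  })
  data <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  allocation <- data.frame(
    participant_id = cohort$params$participant_id,
    schedule_id = vapply(set$schedules, `[[`, character(1), "id")[alloc],
    duration = vapply(set$schedules, `[[`, numeric(1), "duration")[alloc],
    stringsAsFactors = FALSE
  )
  structure(list(data = data, allocation = allocation, set = set),
            class = "combined_dataset")
}

#' Apply individual timing jitter to a cohort
#'
#' Emulates studies with per-participant variability in sampling timings:
#' each non-anchored timepoint is drawn from `N(M, SD)` around the
#' template means, rounded to the 1-min simulation grid, clipped to
#' `[0, 80]` and redrawn (up to 100 times) if the rounded times are not
#' strictly increasing. The templates follow the two study archetypes:
#' medium variability `[0 (0), 21.7 (1.5), 43.9 (2.2), 66.1 (2.6), 80 (0)]`
#' and high variability `[0 (0), 31.8 (5.0), 60.4 (5.6)]`.
#'
#' @param cohort A `sim_cohort`.
#' @param variability `"medium"` or `"high"`.
#' @param seed Integer seed.
#' @return Long-format data frame with actual `time_min` and the template
#'   mean in `nominal_time` (used by conventional analyses that ignore
#'   individual timing).
#' @export
jitter_schedules <- function(cohort, variability = c("medium", "high"), seed = 1) {
  stopifnot(inherits(cohort, "sim_cohort"))
  variability <- match.arg(variability)
  tmpl <- switch(variability,
    medium = list(M = c(0, 21.7, 43.9, 66.1, 80), SD = c(0, 1.5, 2.2, 2.6, 0)),
    high = list(M = c(0, 31.8, 60.4), SD = c(0, 5.0, 5.6)))
  n <- nrow(cohort$params)
  k <- length(tmpl$M)
  with_seed(seed, {
    draw_times <- function() {
      for (attempt in 1:100) {
        tt <- round(rnorm(k, tmpl$M, tmpl$SD))
        tt[tmpl$SD == 0] <- tmpl$M[tmpl$SD == 0]
        tt <- pmin(pmax(tt, 0), 80)
        if (!is.unsorted(tt, strictly = TRUE)) return(tt)
      }
      stop("could not draw strictly increasing jittered timepoints", call. = FALSE)
    }
    rows <- lapply(seq_len(n), function(i) {
      tt <- draw_times()
      idx <- match_times(tt, cohort$times)
      data.frame(participant_id = cohort$params$participant_id[i],
                 study_id = paste0("jitter_", variability),
                 condition = "stress",
                 gender = cohort$params$gender[i],
                 age = NA_real_, test_type = "TSST",
                 time_min = tt,
                 nominal_time = tmpl$M,
                 cortisol_nmol_l = pmax(cohort$obs[i, idx], 0),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
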
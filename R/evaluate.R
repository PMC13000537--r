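# Validation machinery: rank-order accuracy against "true" indicators,
# cross-schedule stability, combined-data comparisons, duration bias, and
# the statistical tests used to compare indicator methods.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; ties receive average ranks.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Correlation coefficient in `[-1, 1]`; `NA` with a warning when
#'   either vector is constant.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Rank-order accuracy of estimated indicators against the truth
#'
#' Joins estimated and true indicator tables by participant and computes,
#' per indicator, the Spearman correlation (rank-order accuracy), the mean
#' absolute error and the bias (mean of true minus estimated values).
#'
#' @param estimates,truth Indicator data frames (as returned by
#'   [indicators_obs()], [indicators_model()], [true_indicators()]) with a
#'   `participant_id` column.
#' @param indicators Indicator columns to evaluate.
#' @return Data frame with one row per indicator: `indicator`, `method`,
#'   `r_s`, `mae`, `bias`, `n`.
#' @export
rank_accuracy <- function(estimates, truth,
                          indicators = c("AUCg", "AUCi", "reactivity", "max_increase")) {
  if (!all(estimates$participant_id %in% truth$participant_id)) {
    offenders <- setdiff(estimates$participant_id, truth$participant_id)
    stop("participants missing from truth: ",
         paste(head(offenders, 5), collapse = ", "),
         if (length(offenders) > 5) ", ...", call. = FALSE)
  }
  m <- match(estimates$participant_id, truth$participant_id)
  do.call(rbind, lapply(indicators, function(ind) {
    est <- estimates[[ind]]
    tru <- truth[[ind]][m]
    ok <- is.finite(est) & is.finite(tru)
    data.frame(indicator = ind,
               method = if ("method" %in% names(estimates)) estimates$method[1] else NA_character_,
               r_s = spearman_cor(est[ok], tru[ok]),
               mae = mean(abs(tru[ok] - est[ok])),
               bias = mean(tru[ok] - est[ok]),
               n = sum(ok), stringsAsFactors = FALSE)
  }))
}

#' Cross-schedule stability of an indicator
#'
#' Computes all pairwise Spearman correlations between the indicator
#' values obtained under different sampling schedules for the same
#' participants; higher mean pairwise correlation means the indicator is
#' more stable across schedules.
#'
#' @param values_by_schedule Numeric matrix or data frame, one row per
#'   participant and one column per schedule.
#' @return List with `pairwise` (data frame of schedule pairs and their
#'   `r_s`) and `mean_r_s` (their mean).
#' @export
stability <- function(values_by_schedule) {
  m <- as.matrix(values_by_schedule)
  k <- ncol(m)
  if (k < 2) stop("need at least 2 schedules", call. = FALSE)
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  r <- apply(pairs, 1, function(p) spearman_cor(m[, p[1]], m[, p[2]]))
  nms <- colnames(m)
  if (is.null(nms)) nms <- paste0("schedule", seq_len(k))
  list(pairwise = data.frame(schedule1 = nms[pairs[, 1]],
                             schedule2 = nms[pairs[, 2]], r_s = r,
                             stringsAsFactors = FALSE),
       mean_r_s = mean(r))
}

#' Fisher-Z averaged correlation
#'
#' `tanh(mean(atanh(r)))`: correlations are transformed to the Fisher Z
#' scale, averaged, and back-transformed.
#'
#' @param r Numeric vector of correlations with `|r| < 1`.
#' @return Averaged correlation.
#' @export
fisher_average <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| = 1 has infinite Fisher transform", call. = FALSE)
  tanh(mean(atanh(r)))
}

#' Paired t-test between two vectors of correlation coefficients
#'
#' Two-sided paired t-test on the raw (untransformed) coefficients, used
#' to compare the rank-order accuracy of two indicator methods across a
#' set of sampling schedules.
#'
#' @param r1,r2 Paired vectors of correlations (length `>= 2`).
#' @return List with `t`, `df`, `p`, `mean_difference`.
#' @export
compare_methods_t <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("paired vectors must have equal length", call. = FALSE)
  if (length(r1) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- r1 - r2
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_difference = 0))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_difference = mean(d)))
  }
  tt <- stats::t.test(r1, r2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = mean(d))
}

#' Exact sign-flip permutation test on paired correlation vectors
#'
#' Compares two methods across replicate combined datasets with an exact
#' paired permutation test: all `2^n` sign assignments of the paired
#' differences are enumerated and the two-sided p-value is the fraction of
#' assignments whose mean difference is at least as extreme as observed.
#'
#' @param r1,r2 Paired vectors (typically length 10, one entry per
#'   combined-data replicate; at most 20).
#' @return List with `statistic` (observed mean difference), `p`, and
#'   `n_permutations`.
#' @export
compare_methods_permutation <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("paired vectors must have equal length", call. = FALSE)
  n <- length(r1)
  if (n < 1 || n > 20) stop("sign-flip enumeration supports 1 to 20 pairs", call. = FALSE)
  d <- r1 - r2
  obs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm <- as.numeric(signs %*% d) / n
  p <- mean(abs(perm) >= abs(obs) - 1e-12)
  list(statistic = obs, p = p, n_permutations = 2^n)
}

#' Z-test between two Fisher-transformed correlations
#'
#' Determines, per indicator and sampling schedule, whether one method's
#' rank-order accuracy differs from another's:
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))` (independent-samples
#' approximation). When the correlation `r12` between the two estimate
#' vectors is supplied, the dependent-correlations correction divides by
#' `sqrt(2 (1 - r12) / (n - 3))` instead.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n Sample size behind each correlation (`> 3`).
#' @param r12 Optional correlation between the two estimates (dependent
#'   variant).
#' @return List with `z` and two-sided `p`.
#' @export
z_test_correlations <- function(r1, r2, n, r12 = NULL) {
  if (n <= 3) stop("`n` must exceed 3", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| = 1 has infinite Fisher transform", call. = FALSE)
  denom <- if (is.null(r12)) sqrt(2 / (n - 3)) else sqrt(2 * (1 - r12) / (n - 3))
  z <- (atanh(r1) - atanh(r2)) / denom
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Correlation of indicator values with sampling duration
#'
#' The core combined-data bias diagnostic: a positive Spearman correlation
#' between an indicator and each participant's allocated sampling duration
#' means the indicator is confounded with study design.
#'
#' @param values Indicator values per participant.
#' @param durations Allocated schedule duration per participant (minutes).
#' @return Spearman correlation; `NA` with a warning if durations do not
#'   vary.
#' @export
duration_bias <- function(values, durations) {
  spearman_cor(values, durations)
}

#' Observation-based indicators after duration harmonization
#'
#' Truncates every participant's series at the latest timepoint common to
#' all schedules in the combined dataset's set (the shortest-schedule
#' cut-off) and recomputes the observation-based indicators, labelled
#' `OBS_s`.
#'
#' @param combined A `combined_dataset` from [build_combined_dataset()].
#' @param peak_time Passed to [indicators_obs()].
#' @return List with `indicators` (method `OBS_s`) and `cutoff` (minutes).
#' @export
obs_truncated <- function(combined, peak_time = 25) {
  stopifnot(inherits(combined, "combined_dataset"))
  times_list <- lapply(combined$set$schedules, `[[`, "times")
  common <- Reduce(intersect, times_list)
  common <- common[common > 0]
  if (length(common) == 0) {
    stop("no common timepoint beyond baseline across schedules", call. = FALSE)
  }
  cutoff <- max(common)
  data <- combined$data[combined$data$time_min <= cutoff, , drop = FALSE]
  list(indicators = indicators_obs(data, peak_time = peak_time,
                                   method_label = "OBS_s"),
       cutoff = cutoff)
}
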
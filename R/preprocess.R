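# Data preparation: baseline correction, measurement-window filtering,
# outlier flagging, responder classification and stratified splitting.
# All functions operate on long-format data with one row per saliva sample
# (see `read_cortisol_csv()` for the column contract) and record exclusions
# as auditable attributes instead of dropping rows silently.

#' Exclusion records attached to a preprocessed dataset
#'
#' @param x A data frame returned by [correct_baseline()] or
#'   [classify_responders()].
#' @return A data frame of exclusion records (possibly empty) with columns
#'   `participant_id`, `condition` and `reason`.
#' @export
exclusions <- function(x) {
  ex <- attr(x, "exclusions")
  if (is.null(ex)) {
    ex <- data.frame(participant_id = character(0), condition = character(0),
                     reason = character(0), stringsAsFactors = FALSE)
  }
  ex
}

series_meta <- function(series) {
  data.frame(
    participant_id = as.character(series$participant_id[1]),
    condition = if ("condition" %in% names(series)) as.character(series$condition[1]) else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Collapse pre-stressor samples to a corrected baseline at t = 0
#'
#' All samples taken in the baseline window (default from -20 to +2 min
#' relative to stressor onset, both ends included) are averaged into a
#' single corrected baseline sample at `t = 0`. Series without any sample
#' in the window cannot be baseline-corrected and are excluded; the
#' exclusion is recorded (see [exclusions()]).
#'
#' @param data Long-format cortisol data frame.
#' @param window Length-2 baseline window in minutes, default `c(-20, 2)`.
#' @return The corrected data frame with an `exclusions` attribute.
#' @export
correct_baseline <- function(data, window = c(-20, 2)) {
  check_long_data(data)
  pieces <- split_series(data)
  out <- vector("list", length(pieces))
  excl <- list()
  for (i in seq_along(pieces)) {
    s <- pieces[[i]][order(pieces[[i]]$time_min), , drop = FALSE]
    in_win <- s$time_min >= window[1] & s$time_min <= window[2]
    if (!any(in_win)) {
      m <- series_meta(s)
      m$reason <- "no baseline sample in window"
      excl[[length(excl) + 1L]] <- m
      next
    }
    base <- s[which(in_win)[1], , drop = FALSE]
    base$time_min <- 0
    base$cortisol_nmol_l <- mean(s$cortisol_nmol_l[in_win])
    out[[i]] <- rbind(base, s[!in_win, , drop = FALSE])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- data[0, , drop = FALSE]
  res <- res[order(series_key(res), res$time_min), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(participant_id = character(0), condition = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  res
}

#' Restrict samples to the measurement window
#'
#' Removes samples outside `[t_min, t_max]` (default the corrected baseline
#' at 0 up to 80 min, both ends included). The number of removed samples is
#' attached as attribute `n_removed`.
#'
#' @param data Baseline-corrected long-format data frame.
#' @param t_min,t_max Window ends in minutes.
#' @return Filtered data frame with attribute `n_removed`.
#' @export
filter_window <- function(data, t_min = 0, t_max = 80) {
  check_long_data(data)
  keep <- data$time_min >= t_min & data$time_min <= t_max
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- attr(data, "exclusions")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Flag extreme cortisol values
#'
#' Flags values deviating from the pooled mean by more than `k` pooled
#' standard deviations (default 5). Mean and SD are computed over the whole
#' input, matching database-level cleaning; apply per study by splitting
#' the data first. Zero-variance input yields no flags.
#'
#' @param x Numeric vector of cortisol values, or a long-format data frame
#'   (then column `cortisol_nmol_l` is used).
#' @param k Threshold in standard deviations.
#' @return Logical vector, `TRUE` where flagged.
#' @export
flag_outliers <- function(x, k = 5) {
  if (is.data.frame(x)) {
    check_long_data(x)
    x <- x$cortisol_nmol_l
  }
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  abs(x - mean(x)) > k * s
}

#' Classify a single series as cortisol responder
#'
#' A responder shows an increase of at least `threshold` nmol/L (default
#' 1.5) from the corrected baseline to the maximum cortisol value within
#' `window` minutes post-onset (default 15 to 45, ends included). Series
#' without any sample in the window are unclassifiable and raise an error.
#'
#' @param time,cortisol Numeric vectors of one baseline-corrected series.
#' @param threshold Minimum increase in nmol/L.
#' @param window Length-2 peak window in minutes.
#' @return `TRUE` or `FALSE`.
#' @export
classify_responder <- function(time, cortisol, threshold = 1.5,
                               window = c(15, 45)) {
  ib <- which(time == 0)
  if (length(ib) != 1) stop("series must have exactly one baseline at t = 0",
                            call. = FALSE)
  in_win <- time >= window[1] & time <= window[2]
  if (!any(in_win)) {
    stop("unclassifiable: no sample between ", window[1], " and ", window[2],
         " min", call. = FALSE)
  }
  max(cortisol[in_win]) - cortisol[ib] >= threshold
}

#' Classify every series in a dataset as responder or non-responder
#'
#' @param data Baseline-corrected long-format data frame.
#' @inheritParams classify_responder
#' @return Data frame with one row per series: `participant_id`,
#'   `condition`, `responder` (logical, `NA` when unclassifiable). Series
#'   without a sample in the peak window are recorded in [exclusions()].
#' @export
classify_responders <- function(data, threshold = 1.5, window = c(15, 45)) {
  check_long_data(data)
  pieces <- split_series(data)
  rows <- vector("list", length(pieces))
  excl <- list()
  for (i in seq_along(pieces)) {
    s <- pieces[[i]]
    m <- series_meta(s)
    m$responder <- tryCatch(
      classify_responder(s$time_min, s$cortisol_nmol_l, threshold, window),
      error = function(e) NA
    )
    if (is.na(m$responder)) {
      e <- series_meta(s)
      e$reason <- "no sample in responder window"
      excl[[length(excl) + 1L]] <- e
    }
    rows[[i]] <- m
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(participant_id = character(0), condition = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  out
}

#' Stratified train/test partition by study
#'
#' Participants are split into training and test sets at the given fraction
#' within every study (stratification by `study_id`), deterministically for
#' a given seed. A study with a single participant contributes it to the
#' training set.
#'
#' @param data Long-format data frame with a `study_id` column.
#' @param fraction Training fraction in `[0, 1]`, default 0.8.
#' @param seed Integer seed controlling the shuffle.
#' @return List with elements `train` and `test` (data frames); their union
#'   is the input and their intersection is empty.
#' @export
stratified_split <- function(data, fraction = 0.8, seed = 1) {
  check_long_data(data)
  if (!"study_id" %in% names(data)) stop("`study_id` column required", call. = FALSE)
  if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]", call. = FALSE)
  ids <- unique(data[, c("participant_id", "study_id")])
  train_ids <- with_seed(seed, {
    unlist(lapply(split(as.character(ids$participant_id), ids$study_id), function(p) {
      p <- sample(p)
      n_train <- if (length(p) == 1) 1L else round(fraction * length(p))
      p[seq_len(min(n_train, length(p)))]
    }), use.names = FALSE)
  })
  in_train <- data$participant_id %in% train_ids
  list(train = data[in_train, , drop = FALSE],
       test = data[!in_train, , drop = FALSE])
}
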
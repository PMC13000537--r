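# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Series key: one cortisol time course ("procedure") is a participant within
# a condition. Data without a condition column is treated as single-condition.
series_key <- function(data) {
  if ("condition" %in% names(data)) {
    paste(data$participant_id, data$condition, sep = "\r")
  } else {
    as.character(data$participant_id)
  }
}

split_series <- function(data) {
  split(data, series_key(data), drop = TRUE)
}

required_columns <- c("participant_id", "time_min", "cortisol_nmol_l")

check_long_data <- function(data) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(required_columns, names(data))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(data)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
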
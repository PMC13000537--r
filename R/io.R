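# Readers, writers, run configuration and the command-line surface.

long_columns <- c("participant_id", "study_id", "condition", "gender", "age",
                  "test_type", "time_min", "cortisol_nmol_l")

#' Read long-format cortisol data from CSV
#'
#' One row per saliva sample with columns `participant_id`, `study_id`,
#' `condition` (stress/control), `gender` (F/M), `age` (years, may be
#' empty), `test_type` (TSST, gTSST, SECPT, MAST, control), `time_min`
#' (minutes relative to stressor onset) and `cortisol_nmol_l`. Validation
#' failures are reported with row numbers; duplicate (participant,
#' condition, time) combinations are an error.
#'
#' @param path CSV file path (UTF-8, header required).
#' @return Validated long-format data frame.
#' @export
read_cortisol_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(required_columns, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & nzchar(raw[[col]]) & is.na(v))
    if (length(bad)) {
      problems <<- c(problems, paste0("non-numeric ", col, " in row(s) ",
                                      paste(head(bad, 5), collapse = ", ")))
    }
    v
  }
  raw$time_min <- num("time_min")
  raw$cortisol_nmol_l <- num("cortisol_nmol_l")
  if ("age" %in% names(raw)) raw$age <- suppressWarnings(as.numeric(raw$age))
  neg <- which(raw$cortisol_nmol_l < 0)
  if (length(neg)) {
    problems <- c(problems, paste0("negative cortisol in row(s) ",
                                   paste(head(neg, 5), collapse = ", ")))
  }
  key <- paste(raw$participant_id,
               if ("condition" %in% names(raw)) raw$condition else "",
               raw$time_min)
  dup <- which(duplicated(key))
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate (participant, time) in row(s) ",
                                   paste(head(dup, 5), collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid cortisol CSV:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  raw
}

#' Write long-format cortisol data to CSV
#'
#' @param data Long-format data frame.
#' @param path Output path.
#' @export
write_cortisol_csv <- function(data, path) {
  check_long_data(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_run_config <- function() {
  list(
    preprocess = list(baseline_window = c(-20, 2), outlier_k = 5,
                      responder_threshold = 1.5, responder_window = c(15, 45),
                      t_min = 0, t_max = 80),
    indicators = list(window = c(0, 80), step = 1, peak_time = 25),
    evaluation = list(replicates = 10),
    simulation = list(n = 500, seed = 1)
  )
}

#' Read a YAML run configuration
#'
#' Unspecified options fall back to the documented defaults (responder
#' threshold 1.5 nmol/L over the 15-45 min window, outlier threshold 5 SD,
#' indicator window 0-80 min, nominal peak 25 min, 10 combined-data
#' replicates).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

write_manifest <- function(dir, command, args, seed) {
  manifest <- list(command = command, arguments = args, seed = seed,
                   package = "cortcurve",
                   version = as.character(utils::packageVersion("cortcurve")),
                   r_version = as.character(getRversion()),
                   date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

cli_usage <- function() {
  cat("usage: cortcurve <command> [options]\n\n",
      "commands:\n",
      "  simulate    --n <int> --seed <int> --out <dir>\n",
      "  preprocess  --in <csv> --out <dir>\n",
      "  fit-asm     --in <csv> --out <dir>\n",
      "  fit-mlm     --in <csv> --out <dir>\n",
      "  indicators  --in <csv> --method obs|asm|mm --out <dir> [--curve <json>]\n",
      "  evaluate    --set duration|frequency|representative|high_variability\n",
      "              --n <int> --replicates <int> --seed <int> --out <dir>\n",
      sep = "")
}

cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    if (i == length(args)) stop("missing value for ", a, call. = FALSE)
    opts[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

#' Command-line interface
#'
#' Thin command-line surface over the package functions (see the
#' `inst/scripts/cortcurve` launcher). Every run writes its outputs plus a
#' `manifest.json` (command, arguments, seed, package and R versions) into
#' the output directory; progress goes to `stderr`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code (0 on success), invisibly.
#' @export
cortcurve_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
    cli_usage()
    return(invisible(0L))
  }
  command <- args[1]
  res <- tryCatch({
    opts <- cli_opts(args[-1])
    out <- opts$out %||% "."
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(opts$seed %||% "1")
    switch(command,
      simulate = {
        cfg <- sim_config(n = as.integer(opts$n %||% "500"), seed = seed)
        cohort <- simulate_cohort(cfg)
        sets <- default_schedule_sets()
        data <- downsample(cohort, sets$representative$schedules[[1]])
        write_cortisol_csv(data, file.path(out, "simulated_observations.csv"))
        utils::write.csv(true_indicators(cohort),
                         file.path(out, "true_indicators.csv"), row.names = FALSE)
        message("simulated ", cfg$n, " individuals -> ", out)
      },
      preprocess = {
        data <- read_cortisol_csv(opts[["in"]])
        data <- filter_window(correct_baseline(data))
        data <- data[!flag_outliers(data), , drop = FALSE]
        write_cortisol_csv(data, file.path(out, "preprocessed.csv"))
        utils::write.csv(exclusions(data), file.path(out, "exclusions.csv"),
                         row.names = FALSE)
        message("preprocessed -> ", out)
      },
      `fit-asm` = {
        data <- read_cortisol_csv(opts[["in"]])
        fit <- fit_asm(data)
        write_population_curve(fit$population, file.path(out, "population_curve.json"))
        utils::write.csv(fit$amplitudes, file.path(out, "amplitudes.csv"),
                         row.names = FALSE)
        message("amplitude scaling model fitted -> ", out)
      },
      `fit-mlm` = {
        data <- read_cortisol_csv(opts[["in"]])
        fit <- fit_mlm(data)
        utils::write.csv(fit$coefficients, file.path(out, "fixed_effects.csv"),
                         row.names = TRUE)
        utils::write.csv(fit$psi, file.path(out, "individual_parameters.csv"),
                         row.names = FALSE)
        message("multilevel model fitted -> ", out)
      },
      indicators = {
        data <- read_cortisol_csv(opts[["in"]])
        method <- opts$method %||% "obs"
        pop <- if (!is.null(opts$curve)) read_population_curve(opts$curve)
        if (method == "asm" && is.null(pop) && is.null(tryCatch(
          classify_responders(data), error = function(e) NULL))) {
          stop("no fitted population curve: pass --curve or provide data with a 15-45 min sample",
               call. = FALSE)
        }
        tab <- indicator_table(data, method = method, pop = pop)
        utils::write.csv(tab, file.path(out, paste0("indicators_", method, ".csv")),
                         row.names = FALSE)
        message("indicators (", method, ") -> ", out)
      },
      evaluate = {
        sets <- default_schedule_sets()
        set_name <- opts$set %||% "duration"
        if (!set_name %in% names(sets)) stop("unknown schedule set: ", set_name,
                                             call. = FALSE)
        rep_n <- as.integer(opts$replicates %||% "10")
        cohort <- simulate_cohort(sim_config(n = as.integer(opts$n %||% "500"),
                                             seed = seed))
        truth <- true_indicators(cohort)
        rows <- list()
        for (r in seq_len(rep_n)) {
          comb <- build_combined_dataset(cohort, sets[[set_name]], seed = seed + r)
          for (method in c("obs", "asm", "mm")) {
            tab <- indicator_table(comb$data, method = method)
            acc <- rank_accuracy(tab, truth)
            acc$replicate <- r
            rows[[length(rows) + 1L]] <- acc
          }
          trunc <- tryCatch(obs_truncated(comb), error = function(e) NULL)
          if (!is.null(trunc)) {
            acc <- rank_accuracy(trunc$indicators, truth)
            acc$replicate <- r
            rows[[length(rows) + 1L]] <- acc
          }
        }
        report <- do.call(rbind, rows)
        utils::write.csv(report, file.path(out, "evaluation.csv"), row.names = FALSE)
        message("evaluation (", set_name, ", ", rep_n, " replicates) -> ", out)
      },
      {
        cli_usage()
        stop("unknown command: ", command, call. = FALSE)
      })
    write_manifest(out, command, args[-1], seed)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
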
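# Shared fixtures, generated in code.

# one tidy long-format series
make_series <- function(id = "p1", times, cortisol, study = "s1",
                        condition = "stress", gender = "F", test = "TSST") {
  data.frame(participant_id = id, study_id = study, condition = condition,
             gender = gender, age = 25, test_type = test,
             time_min = times, cortisol_nmol_l = cortisol,
             stringsAsFactors = FALSE)
}

# noise-free cohort drawn from a single response curve family
make_noise_free_cohort <- function(n = 30, times = c(0, 10, 20, 30, 45, 60, 80),
                                   alpha = 3, beta = 0.1, A = 150, b0 = 5,
                                   amplitudes = NULL, seed = 1) {
  if (is.null(amplitudes)) {
    amplitudes <- withr_seed(seed, stats::rlnorm(n, log(A), 0.5))
  }
  do.call(rbind, lapply(seq_len(n), function(i) {
    crv <- response_curve(alpha, beta, A = amplitudes[i], b0 = b0)
    make_series(sprintf("p%03d", i), times, eval_curve(crv, times))
  }))
}

# seed-scoped RNG without touching the session RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
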
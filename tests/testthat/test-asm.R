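test_that("population curve parameters are recovered from noise-free data", {
  true <- list(alpha = 3.1, beta = 0.12, A = 160, b0 = 5.2)
  d <- make_noise_free_cohort(n = 25, alpha = true$alpha, beta = true$beta,
                              A = true$A, b0 = true$b0,
                              amplitudes = rep(true$A, 25))
  pop <- fit_population_curve(d)
  est <- coef(pop)
  for (p in c("alpha", "beta", "A", "b0")) {
    expect_lt(abs(est[[p]] - true[[p]]) / true[[p]], 1e-4)
  }
})

test_that("population amplitude vanishes for flat cohorts", {
  d <- do.call(rbind, lapply(1:10, function(i) {
    make_series(sprintf("p%d", i), c(0, 15, 30, 45, 60), rep(5 + i / 10, 5))
  }))
  pop <- fit_population_curve(d)
  expect_lt(abs(coef(pop)[["A"]]), 1e-4)
})

test_that("population amplitude survives white noise at cohort scale", {
  true_A <- 150
  amps <- rep(true_A, 500)
  clean <- make_noise_free_cohort(n = 500, A = true_A, amplitudes = amps)
  noisy <- clean
  noisy$cortisol_nmol_l <- clean$cortisol_nmol_l +
    withr_seed(8, stats::rnorm(nrow(clean), 0, 1))
  noisy$cortisol_nmol_l <- pmax(noisy$cortisol_nmol_l, 0)
  pop <- fit_population_curve(noisy)
  expect_lt(abs(coef(pop)[["A"]] - true_A) / true_A, 0.05)
})

test_that("model selection prefers the four-parameter curve when extras are absent", {
  d <- make_noise_free_cohort(n = 40, seed = 3)
  d$cortisol_nmol_l <- d$cortisol_nmol_l + withr_seed(5, stats::rnorm(nrow(d), 0, 0.3))
  d$cortisol_nmol_l <- pmax(d$cortisol_nmol_l, 0)
  sel <- select_population_model(d)
  expect_equal(sel$chosen, "basic")
})

test_that("model selection detects a strong linear drift", {
  tt <- c(0, 10, 20, 30, 45, 60, 80)
  d <- do.call(rbind, lapply(1:40, function(i) {
    crv <- response_curve(3, 0.1, A = 150, b0 = 8, b1 = -0.05)
    make_series(sprintf("p%02d", i), tt,
                pmax(eval_curve(crv, tt) +
                       withr_seed(100 + i, stats::rnorm(length(tt), 0, 0.3)), 0))
  }))
  sel <- select_population_model(d, b0 = 8)
  expect_equal(sel$chosen, "extended")
})

test_that("individual amplitude has the closed least-squares form", {
  pop <- fit_population_curve(make_noise_free_cohort(n = 20, seed = 6))
  # exact representation: amplitude recovered exactly
  tt <- c(0, 12, 27, 44, 61)
  y <- 77 * gamma_density(tt, coef(pop)[["alpha"]], coef(pop)[["beta"]]) + 4.4
  fit <- fit_individual_amplitude(tt, y, pop)
  expect_equal(fit$A, 77, tolerance = 1e-9)
  expect_equal(fit$baseline, 4.4)
  # constant series: zero amplitude
  flat <- fit_individual_amplitude(c(0, 20, 40), rep(6, 3), pop)
  expect_equal(flat$A, 0)
  # single post-baseline point: ratio y_norm / f
  f30 <- gamma_density(30, coef(pop)[["alpha"]], coef(pop)[["beta"]])
  one <- fit_individual_amplitude(c(0, 30), c(2, 2 + 3), pop)
  expect_equal(one$A, 3 / f30, tolerance = 1e-12)
  expect_error(fit_individual_amplitude(c(0), c(5), pop), "post-baseline")
})

test_that("amplitude fitting is shift- and scale-equivariant", {
  pop <- fit_population_curve(make_noise_free_cohort(n = 20, seed = 7))
  tt <- c(0, 10, 25, 40, 60)
  y <- withr_seed(9, 5 + 120 * gamma_density(tt, 3, 0.1) + stats::rnorm(5, 0, 0.5))
  base <- fit_individual_amplitude(tt, y, pop)$A
  # adding a constant leaves the amplitude unchanged
  expect_equal(fit_individual_amplitude(tt, y + 2.5, pop)$A, base, tolerance = 1e-9)
  # scaling the deviations scales the amplitude
  y2 <- y[1] + 3 * (y - y[1])
  expect_equal(fit_individual_amplitude(tt, y2, pop)$A, 3 * base, tolerance = 1e-9)
})

test_that("closed-form amplitude matches a brute-force 1-D minimizer", {
  pop <- fit_population_curve(make_noise_free_cohort(n = 20, seed = 10))
  tt <- c(0, 15, 30, 50, 70)
  y <- withr_seed(11, 6 + 90 * gamma_density(tt, 3, 0.1) + stats::rnorm(5, 0, 1))
  A_hat <- fit_individual_amplitude(tt, y, pop)$A
  f <- gamma_density(tt[-1], coef(pop)[["alpha"]], coef(pop)[["beta"]])
  sse <- function(A) sum((y[-1] - y[1] - A * f)^2)
  grid <- seq(A_hat - 50, A_hat + 50, by = 0.01)
  expect_equal(A_hat, grid[which.min(vapply(grid, sse, numeric(1)))],
               tolerance = 0.01)
})

test_that("control-style declining cohorts yield amplitudes centred at zero", {
  pop <- fit_population_curve(make_noise_free_cohort(n = 20, seed = 12))
  tt <- c(0, 15, 30, 50, 70)
  A_hats <- vapply(1:200, function(i) {
    y <- withr_seed(2000 + i, 6 + stats::rnorm(5, 0, 1))
    fit_individual_amplitude(tt, y, pop)$A
  }, numeric(1))
  expect_lt(abs(mean(A_hats)), stats::sd(A_hats) / sqrt(200) * 4)
})

test_that("the full amplitude scaling pipeline reports per-series diagnostics", {
  co <- simulate_cohort(sim_config(n = 80, seed = 13))
  d <- downsample(co, sampling_schedule(c(0, 15, 25, 40, 60, 80)))
  fit <- fit_asm(d)
  expect_s3_class(fit, "asm_fit")
  expect_equal(nrow(fit$amplitudes), 80)
  expect_true(all(is.finite(fit$amplitudes$A)))
  expect_true(all(fit$amplitudes$mae >= 0))
  # predictions at t = 0 equal the observed baseline
  pred0 <- predict(fit, times = 0)
  base <- fit$amplitudes$baseline[match(rownames(pred0), fit$amplitudes$participant_id)]
  expect_equal(unname(pred0[, 1]), base, tolerance = 1e-6)
})

test_that("population curves round-trip through JSON", {
  pop <- fit_population_curve(make_noise_free_cohort(n = 20, seed = 14))
  path <- tempfile(fileext = ".json")
  write_population_curve(pop, path)
  back <- read_population_curve(path)
  expect_equal(coef(back), coef(pop), tolerance = 1e-12)
  expect_equal(back$n_obs, pop$n_obs)
  unlink(path)
})
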
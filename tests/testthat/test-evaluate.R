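test_that("spearman correlation matches a brute-force mid-rank oracle", {
  rank_oracle <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  withr_seed(99, {
    for (i in 1:1000) {
      n <- sample(5:40, 1)
      # heavy ties: integer-valued draws
      x <- sample(1:6, n, replace = TRUE) + stats::rnorm(n, 0, 0.01 * (i %% 2))
      y <- sample(1:6, n, replace = TRUE)
      expect_equal(spearman_cor(x, y), rank_oracle(x, y), tolerance = 1e-12)
    }
  })
  expect_equal(spearman_cor(1:10, exp(1:10)), 1)
  expect_equal(spearman_cor(1:10, -(1:10)), -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("rank accuracy reports perfect, shifted and permuted estimates correctly", {
  truth <- data.frame(participant_id = sprintf("p%05d", 1:10000),
                      method = "TRUE",
                      AUCg = withr_seed(1, stats::rnorm(10000, 500, 100)))
  est <- truth; est$method <- "OBS"
  acc <- rank_accuracy(est, truth, "AUCg")
  expect_equal(acc$r_s, 1)
  expect_equal(acc$mae, 0)
  expect_equal(acc$bias, 0)
  shifted <- est; shifted$AUCg <- est$AUCg - 25
  acc2 <- rank_accuracy(shifted, truth, "AUCg")
  expect_equal(acc2$r_s, 1)
  expect_equal(acc2$bias, 25)
  permuted <- est; permuted$AUCg <- withr_seed(2, sample(est$AUCg))
  expect_lt(abs(rank_accuracy(permuted, truth, "AUCg")$r_s), 0.03)
  bad <- est; bad$participant_id[1] <- "stranger"
  expect_error(rank_accuracy(bad, truth, "AUCg"), "stranger")
})

test_that("stability summarizes all schedule pairs", {
  m <- cbind(s1 = 1:20, s2 = (1:20)^2, s3 = log(1:20))
  st <- stability(m)
  expect_equal(nrow(st$pairwise), 3)
  expect_equal(st$mean_r_s, 1)
  m4 <- cbind(m, s4 = 20:1)
  expect_equal(nrow(stability(m4)$pairwise), 6)
  expect_error(stability(m[, 1, drop = FALSE]), "2 schedules")
})

test_that("fisher averaging is the tanh of mean atanh", {
  expect_equal(fisher_average(c(0.7, 0.7, 0.7)), 0.7)
  expect_equal(fisher_average(c(0.5, -0.5)), 0)
  expect_equal(fisher_average(c(0.9, 0.8)),
               tanh((atanh(0.9) + atanh(0.8)) / 2), tolerance = 1e-12)
  expect_lt(abs(fisher_average(c(0.9, 0.8)) - 0.857), 0.0015)
  expect_error(fisher_average(c(0.5, 1)), "infinite")
})

test_that("paired t comparison of accuracy vectors handles degenerate cases", {
  r <- c(0.9, 0.92, 0.88, 0.95)
  same <- compare_methods_t(r, r)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- compare_methods_t(r + 0.02, r)
  expect_equal(shifted$p, 0)
  expect_equal(compare_methods_t(c(0.9, 0.8, 0.85, 0.7, 0.95, 0.88,
                                   0.92, 0.81, 0.86, 0.9, 0.83, 0.87),
                                 c(0.8, 0.7, 0.8, 0.65, 0.9, 0.8,
                                   0.85, 0.7, 0.8, 0.85, 0.8, 0.8))$df, 11)
  noisy <- withr_seed(3, compare_methods_t(r + stats::rnorm(4, 0.1, 0.005), r))
  expect_lt(noisy$p, 0.05)
})

test_that("exact sign-flip permutation enumerates all 2^n assignments", {
  expect_equal(compare_methods_permutation(rep(0.9, 10), rep(0.9, 10))$p, 1)
  allpos <- compare_methods_permutation(seq(0.91, 0.95, length.out = 10),
                                        seq(0.81, 0.85, length.out = 10))
  expect_equal(allpos$p, 2 / 1024)
  expect_equal(allpos$n_permutations, 1024)
  alt <- compare_methods_permutation(c(0.9, 0.8, 0.9, 0.8), c(0.8, 0.9, 0.8, 0.9))
  expect_gt(alt$p, 0.5)
  expect_error(compare_methods_permutation(1:2 / 10, 1:3 / 10), "equal length")
})

test_that("exact permutation p matches Monte-Carlo permutation within binomial error", {
  d1 <- c(0.92, 0.89, 0.94, 0.91, 0.90, 0.93, 0.88, 0.95, 0.91, 0.92)
  d2 <- c(0.90, 0.90, 0.92, 0.92, 0.88, 0.91, 0.89, 0.93, 0.92, 0.90)
  exact <- compare_methods_permutation(d1, d2)$p
  d <- d1 - d2
  mc <- withr_seed(7, {
    obs <- mean(d)
    hits <- 0L
    for (b in 1:1e5) {
      s <- sample(c(-1, 1), 10, replace = TRUE)
      hits <- hits + (abs(mean(s * d)) >= abs(obs) - 1e-12)
    }
    hits / 1e5
  })
  expect_lt(abs(exact - mc), 3 * sqrt(exact * (1 - exact) / 1e5) + 1e-4)
})

test_that("Fisher Z-test compares two accuracy coefficients", {
  expect_equal(z_test_correlations(0.9, 0.9, 100)$z, 0)
  expect_equal(z_test_correlations(0.9, 0.9, 100)$p, 1)
  zt <- z_test_correlations(0.95, 0.90, 10000)
  expect_equal(zt$z, (atanh(0.95) - atanh(0.90)) / sqrt(2 / 9997))
  expect_equal(round(zt$z, 1), 25.4)
  expect_lt(zt$p, 1e-10)
  expect_equal(z_test_correlations(0.9, 0.95, 10000)$z, -zt$z)
  expect_error(z_test_correlations(0.5, 0.4, 3), "exceed 3")
  # dependent-correlations variant tightens the denominator
  dep <- z_test_correlations(0.95, 0.90, 10000, r12 = 0.8)
  expect_gt(abs(dep$z), abs(zt$z))
})

test_that("duration bias is zero for schedule-independent values", {
  durations <- rep(c(40, 60, 80), length.out = 999)
  vals <- withr_seed(13, stats::rnorm(999))
  expect_lt(abs(duration_bias(vals, durations)), 0.07)
  expect_warning(duration_bias(vals, rep(40, 999)), "constant")
})

test_that("duration harmonization truncates at the latest common timepoint", {
  co <- simulate_cohort(sim_config(n = 60, seed = 19))
  set <- default_schedule_sets()$duration
  comb <- build_combined_dataset(co, set, seed = 2)
  tr <- obs_truncated(comb)
  expect_equal(tr$cutoff, 40)
  expect_true(all(tr$indicators$method == "OBS_s"))
  # after truncation every series spans the same duration
  spans <- tapply(comb$data$time_min[comb$data$time_min <= 40],
                  comb$data$participant_id[comb$data$time_min <= 40], max)
  expect_true(all(spans == 40))
  # single-schedule data: OBS_s equals OBS
  one <- schedule_set("duration", list(sampling_schedule(c(0, 15, 25, 40))))
  comb1 <- build_combined_dataset(co, one, seed = 3)
  tr1 <- obs_truncated(comb1)
  obs1 <- indicators_obs(comb1$data)
  expect_equal(tr1$indicators$AUCg, obs1$AUCg)
})
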
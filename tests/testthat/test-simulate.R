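test_that("noise-free simulation reproduces the deterministic curves", {
  cfg <- sim_config(n = 12, sigma_white = 0, sigma_red = 0,
                    nonresponder_fraction = 0, seed = 2)
  co <- simulate_cohort(cfg)
  p <- co$params[3, ]
  expect_equal(co$red[3, ],
               eval_curve(response_curve(p$alpha, p$beta, p$A, p$b0), co$times))
  expect_equal(co$obs, co$red)
})

test_that("white noise has the configured spread and cohorts are reproducible", {
  cfg <- sim_config(n = 2000, sigma_white = 1, seed = 6)
  co <- simulate_cohort(cfg)
  resid <- co$obs - co$red
  expect_equal(stats::sd(resid), 1, tolerance = 0.02)
  co2 <- simulate_cohort(cfg)
  expect_identical(co$obs, co2$obs)
  expect_identical(co$params, co2$params)
})

test_that("red-noise deviations approach the Ornstein-Uhlenbeck stationary spread", {
  cfg <- sim_config(n = 400, sigma_white = 0, A_meanlog = log(1e-9),
                    A_sdlog = 1e-6, nonresponder_fraction = 0,
                    b0_sd = 1e-9, theta_red = 0.2, sigma_red = 0.63, seed = 8)
  co <- simulate_cohort(cfg)
  # flat structural curve: deviations at the final timepoint are stationary OU
  dev <- co$red[, ncol(co$red)] - co$params$b0
  target <- cfg$sigma_red / sqrt(2 * cfg$theta_red)
  expect_equal(stats::sd(dev), target, tolerance = 0.05 * target + 0.02)
})

test_that("cohort mean trajectory converges to the population structural mean", {
  cfg <- sim_config(n = 5000, seed = 12)
  co <- simulate_cohort(cfg)
  post <- co$times >= 0
  emp <- colMeans(co$obs[, post])
  struct <- sapply(co$times[post], function(tj) {
    f <- if (tj > 0) stats::dgamma(tj, shape = co$params$alpha,
                                   rate = co$params$beta) else rep(0, nrow(co$params))
    mean(co$params$A * f + co$params$b0)
  })
  expect_lt(max(abs(emp - struct)) / max(struct), 0.02)
})

test_that("schedules validate ordering, span and minimum duration", {
  s <- sampling_schedule(c(0, 20, 40, 60, 80))
  expect_equal(s$duration, 80)
  expect_error(sampling_schedule(c(10, 40)), "baseline")
  expect_error(sampling_schedule(c(0, 40, 30)), "increasing")
  expect_error(sampling_schedule(c(0, 90)), "0, 80")
  expect_error(sampling_schedule(c(0, 20)), "minimum")
  expect_silent(sampling_schedule(c(0, 20), min_duration = 20))
})

test_that("built-in schedule sets honour their documented structure", {
  sets <- default_schedule_sets()
  expect_length(sets$representative$schedules, 12)
  expect_length(sets$high_variability$schedules, 5)
  # duration set: shared timepoints up to the shortest duration
  durs <- lapply(sets$duration$schedules, `[[`, "times")
  shortest <- durs[[which.min(vapply(durs, max, numeric(1)))]]
  for (d in durs) expect_equal(d[d <= max(shortest)], shortest)
  # the very sparse two-sample design is present
  expect_true(any(vapply(sets$high_variability$schedules,
                         function(s) identical(s$times, c(0, 30)), logical(1))))
})

test_that("downsampling extracts exactly the scheduled observations", {
  co <- simulate_cohort(sim_config(n = 15, seed = 3))
  sch <- sampling_schedule(c(0, 20, 40, 60, 80))
  d <- downsample(co, sch)
  expect_equal(nrow(d), 15 * 5)
  expect_equal(sort(unique(d$time_min)), c(0, 20, 40, 60, 80))
  i <- which(co$params$participant_id == "sim00007")
  got <- d$cortisol_nmol_l[d$participant_id == "sim00007"]
  expect_equal(got, pmax(co$obs[i, match(sch$times, co$times)], 0))
  expect_error(downsample(co, sampling_schedule(c(0, 12.5, 40), min_duration = 30)),
               "grid")
})

test_that("combined datasets allocate schedules uniformly and reproducibly", {
  co <- simulate_cohort(sim_config(n = 4000, seed = 5))
  set <- default_schedule_sets()$duration
  comb <- build_combined_dataset(co, set, seed = 9)
  counts <- table(comb$allocation$schedule_id)
  expect_length(counts, 3)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  comb2 <- build_combined_dataset(co, set, seed = 9)
  expect_identical(comb$allocation, comb2$allocation)
  comb3 <- build_combined_dataset(co, set, seed = 10)
  expect_false(identical(comb$allocation$schedule_id, comb3$allocation$schedule_id))
  # single-schedule set: everyone shares it
  one <- schedule_set("duration", list(sampling_schedule(c(0, 20, 40))))
  expect_equal(unique(build_combined_dataset(co, one, seed = 1)$allocation$schedule_id),
               one$schedules[[1]]$id)
})

test_that("timing jitter reproduces the template means and stays on grid", {
  co <- simulate_cohort(sim_config(n = 3000, seed = 7))
  jd <- jitter_schedules(co, "medium", seed = 4)
  second <- jd$time_min[jd$nominal_time == 21.7]
  expect_equal(mean(second), 21.7, tolerance = 0.1)
  expect_true(all(jd$time_min == round(jd$time_min)))
  # anchored timepoints are identical across individuals
  expect_true(all(jd$time_min[jd$nominal_time == 0] == 0))
  expect_true(all(jd$time_min[jd$nominal_time == 80] == 80))
  jh <- jitter_schedules(co[1:200], "high", seed = 4)
  expect_equal(unique(table(jh$participant_id)), 3L)
})

test_that("conventional indicators can use schedule-mean timings on jittered data", {
  co <- simulate_cohort(sim_config(n = 50, seed = 23))
  jd <- jitter_schedules(co, "medium", seed = 5)
  nominal <- indicators_obs(jd, use_nominal_times = TRUE)
  actual <- indicators_obs(jd)
  expect_equal(nrow(nominal), 50)
  # interior timepoints differ across individuals, so the trapezoid weights
  # (and hence AUCg) differ between nominal and actual timings
  expect_false(isTRUE(all.equal(nominal$AUCg, actual$AUCg)))
  interior <- jd$time_min[jd$nominal_time == 43.9]
  expect_gt(stats::sd(interior), 0)
})
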
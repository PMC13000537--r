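# The multilevel fitter is exercised at small cohort sizes here; the
# cohort-scale behaviour is covered by the acceptance suite.

mu_ref <- c(alpha = log(3.2), beta = log(0.115), A = log(200), b0 = 5.5)
om_ref <- c(alpha = 0.03, beta = 0.03, A = 0.4, b0 = 1.4)

test_that("laplace estimator matches closed-form ML on a linear submodel", {
  # only the amplitude is random (normal family): the model is linear in
  # the random effect and the marginal likelihood has a closed form
  n <- 60
  tt <- c(0, 10, 20, 30, 40, 60)
  f <- gamma_density(tt, 3, 0.1)
  A <- withr_seed(5, stats::rnorm(n, 120, 30))
  d <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(participant_id = sprintf("p%03d", i), time_min = tt,
               cortisol_nmol_l = A[i] * f + 5 +
                 withr_seed(500 + i, stats::rnorm(length(tt), 0, 1)))
  }))
  sp <- mlm_spec(parameters = "A", families = c(A = "normal"),
                 fixed = list(alpha = 3, beta = 0.1, b0 = 5, b1 = 0, dT = 0),
                 method = "laplace", max_iter = 500, tol = 1e-10)
  fit <- fit_mlm(d, spec = sp)
  # closed-form marginal ML oracle
  nll <- function(p) {
    mu <- p[1]; om <- exp(p[2]); s2 <- exp(p[3])
    V <- om * outer(f, f) + diag(s2, length(tt))
    Vi <- solve(V); ld <- determinant(V)$modulus
    tot <- 0
    for (i in seq_len(n)) {
      yy <- d$cortisol_nmol_l[d$participant_id == sprintf("p%03d", i)] - 5 - mu * f
      tot <- tot + 0.5 * (ld + t(yy) %*% Vi %*% yy + length(tt) * log(2 * pi))
    }
    as.numeric(tot)
  }
  o <- stats::optim(c(100, log(800), log(1)), nll, method = "BFGS")
  expect_lt(abs(fit$coefficients["A.(Intercept)", "estimate"] - o$par[1]) /
              abs(o$par[1]), 1e-3)
  expect_lt(abs(fit$omega[["A"]] - exp(o$par[2])) / exp(o$par[2]), 1e-3)
  expect_lt(abs(-fit$logLik - o$value) / o$value, 1e-3)
})

test_that("fixed effects are recovered within two standard errors", {
  d <- simulate_mlm_cohort(120, c(0, 15, 25, 40, 60, 80), mu_ref, om_ref,
                           sigma = 1, seed = 11)
  fit <- fit_mlm(d, seed = 1)
  co <- fit$coefficients
  for (p in names(mu_ref)) {
    row <- co[paste0(p, ".(Intercept)"), ]
    expect_lt(abs(row$estimate - mu_ref[[p]]) / row$se, 2)
  }
  expect_lt(abs(fit$sigma - 1), 0.1)
})

test_that("SAEM fits are exactly reproducible from the seed", {
  d <- simulate_mlm_cohort(30, c(0, 15, 30, 60), mu_ref, om_ref, sigma = 1,
                           seed = 3)
  f1 <- fit_mlm(d, seed = 7)
  f2 <- fit_mlm(d, seed = 7)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$psi$A, f2$psi$A)
})

test_that("empirical-Bayes estimates shrink fully when subjects are identical", {
  tt <- c(0, 10, 25, 40, 60, 80)
  crv <- response_curve(3, 0.1, A = 150, b0 = 5)
  d <- do.call(rbind, lapply(1:25, function(i) {
    data.frame(participant_id = sprintf("p%02d", i), time_min = tt,
               cortisol_nmol_l = eval_curve(crv, tt))
  }))
  fit <- fit_mlm(d, spec = mlm_spec(method = "laplace"))
  # no between-subject variance: everyone sits at the population mean
  expect_lt(max(abs(fit$phi - fit$phi_mean)), 0.05)
  expect_lt(stats::sd(fit$psi$A), 1)
})

test_that("shrinkage toward the mean weakens as data per subject grow", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    truth_phi <- mu_ref + 1.5 * sqrt(om_ref)
    psi_t <- c(exp(truth_phi[1:3]), truth_phi[4])
    crv <- response_curve(psi_t[1], psi_t[2], A = psi_t[3], b0 = psi_t[4])
    mk <- function(id, tt) {
      data.frame(participant_id = id, time_min = tt,
                 cortisol_nmol_l = eval_curve(crv, tt) +
                   stats::rnorm(length(tt), 0, 1))
    }
    d <- withr_seed(100 + s, {
      bg <- simulate_mlm_cohort(40, c(0, 15, 25, 40, 60, 80), mu_ref, om_ref,
                                sigma = 1, seed = 1000 + s)
      rbind(bg[, c("participant_id", "time_min", "cortisol_nmol_l")],
            mk("sparse", c(0, 5)),
            mk("dense", c(0, 5, 10, 15, 20, 25, 30, 40, 50, 55, 60, 70, 80)))
    })
    fit <- fit_mlm(d, spec = mlm_spec(method = "laplace"))
    # distance over the response-shape parameters: their information scales
    # with post-baseline sampling, unlike b0 which the baseline sample pins
    # in both designs
    ksel <- match(c("alpha", "beta", "A"), fit$spec$parameters)
    dist <- function(id) {
      i <- which(fit$psi$participant_id == id)
      sqrt(sum(((fit$phi[i, ksel] - fit$phi_mean[i, ksel]) /
                  sqrt(fit$omega[ksel]))^2))
    }
    hits <- hits + (dist("sparse") < dist("dense"))
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("individual predictions recover a densely sampled noise-free subject", {
  # a well-sampled subject with many observations escapes its prior
  tt <- seq(0, 80, by = 5)
  truth <- response_curve(3.4, 0.13, A = 230, b0 = 6)
  d <- rbind(
    simulate_mlm_cohort(30, c(0, 15, 25, 40, 60, 80), mu_ref, om_ref,
                        sigma = 1, seed = 6)[, c("participant_id", "time_min", "cortisol_nmol_l")],
    data.frame(participant_id = "target", time_min = tt,
               cortisol_nmol_l = eval_curve(truth, tt)))
  fit <- fit_mlm(d, spec = mlm_spec(method = "laplace"))
  crv <- predict_individual(fit, "target")
  grid <- time_grid(0, 80)
  expect_lt(max(abs(eval_curve(crv, grid) - eval_curve(truth, grid))) /
              max(eval_curve(truth, grid)), 0.02)
  expect_error(predict_individual(fit, "nobody"), "unknown")
})

test_that("empirical-Bayes predictions beat the population mean curve in-sample", {
  d <- simulate_mlm_cohort(60, c(0, 15, 25, 40, 60, 80), mu_ref, om_ref,
                           sigma = 1, seed = 21)
  fit <- fit_mlm(d, spec = mlm_spec(method = "laplace"))
  pop_curve <- response_curve(exp(coef(fit)[["alpha.(Intercept)"]]),
                              exp(coef(fit)[["beta.(Intercept)"]]),
                              A = exp(coef(fit)[["A.(Intercept)"]]),
                              b0 = coef(fit)[["b0.(Intercept)"]])
  pop_pred <- eval_curve(pop_curve, d$time_min)
  pop_mae <- mean(abs(d$cortisol_nmol_l - pop_pred))
  expect_lt(mean(fit$psi$mae), pop_mae)
})

test_that("multilevel fit has lower in-sample error than amplitude scaling", {
  co <- simulate_cohort(sim_config(n = 100, seed = 17))
  d <- downsample(co, sampling_schedule(c(0, 15, 25, 40, 60, 80)))
  fm <- fit_mlm(d, spec = mlm_spec(method = "laplace"))
  fa <- fit_asm(d)
  expect_lt(mean(fm$psi$mae), mean(fa$amplitudes$mae, na.rm = TRUE))
})

test_that("gender covariate effects on amplitude are estimated and retained", {
  d <- simulate_mlm_cohort(150, c(0, 15, 25, 40, 60, 80), mu_ref, om_ref,
                           sigma = 1, seed = 31,
                           covariate_effects = list(A = c(genderM = 0.5)))
  sp0 <- mlm_spec(method = "laplace")
  sp1 <- mlm_spec(covariates = list(A = "gender"), method = "laplace")
  f0 <- fit_mlm(d, spec = sp0)
  f1 <- fit_mlm(d, spec = sp1)
  est <- f1$coefficients["A.genderM", ]
  expect_lt(abs(est$estimate - 0.5) / est$se, 2.5)
  dec <- evaluate_covariate(f1, f0, "A.genderM")
  expect_true(dec$retain)
  expect_lt(dec$p, 0.05)
})

test_that("covariate retention needs significance, stability and BIC together", {
  # a null covariate effect must be dropped
  d <- simulate_mlm_cohort(80, c(0, 15, 25, 40, 60, 80), mu_ref, om_ref,
                           sigma = 1, seed = 41)
  f0 <- fit_mlm(d, spec = mlm_spec(method = "laplace"))
  f1 <- fit_mlm(d, spec = mlm_spec(covariates = list(b0 = "gender"),
                                   method = "laplace"))
  dec <- evaluate_covariate(f1, f0, "b0.genderM")
  expect_false(dec$retain)
})

test_that("series with fewer than two samples are excluded from the fit", {
  d <- rbind(simulate_mlm_cohort(20, c(0, 20, 45, 70), mu_ref, om_ref,
                                 sigma = 1, seed = 51)[, c("participant_id", "time_min", "cortisol_nmol_l")],
             data.frame(participant_id = "baseline_only", time_min = 0,
                        cortisol_nmol_l = 5))
  fit <- fit_mlm(d, spec = mlm_spec(method = "laplace"))
  expect_equal(fit$n_subjects, 20)
  expect_true("baseline_only" %in% fit$exclusions$participant_id)
  expect_error(predict_individual(fit, "baseline_only"), "unknown")
})

test_that("fitted multilevel models expose likelihood and simulation methods", {
  d <- simulate_mlm_cohort(25, c(0, 15, 30, 60), mu_ref, om_ref, sigma = 1,
                           seed = 61)
  fit <- fit_mlm(d, spec = mlm_spec(method = "laplace"))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "nobs"), nrow(d))
  expect_equal(stats::BIC(ll), fit$bic)
  sims <- simulate(fit, nsim = 2, seed = 3, times = c(0, 20, 40))
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), 25 * 3)
  sims2 <- simulate(fit, nsim = 2, seed = 3, times = c(0, 20, 40))
  expect_identical(sims[[1]]$cortisol_nmol_l, sims2[[1]]$cortisol_nmol_l)
})
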
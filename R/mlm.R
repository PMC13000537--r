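# Nonlinear multilevel model of the gamma-kernel response curve.
#
# The latent parameterization works on a transformed scale phi:
# log(alpha), log(beta), log(A) for positivity-constrained parameters
# (log-normal random effects) and the identity scale for b0, b1, dT
# (normal random effects). Per subject i,
#   phi_i = X_i theta + eta_i,   eta_i ~ N(0, diag(omega)),
#   y_ij  = g(t_ij; psi(phi_i)) + eps_ij,  eps_ij ~ N(0, a^2)  ("constant"
# error model).
#
# Two estimators are provided. The default is a stochastic-approximation
# EM (SAEM): the E-step draws from each subject's conditional posterior by
# componentwise random-walk Metropolis (vectorized across subjects), and
# sufficient statistics are smoothed with step sizes gamma_k = 1 during
# burn-in and 1/(k - burn) afterwards; this avoids the linearization bias
# that first-order methods show with few samples per subject. The
# alternative ("laplace") is a deterministic Laplace-EM whose E-step is a
# damped Gauss-Newton posterior mode with Gaussian curvature; it is exact
# for models that are linear in the random effects. Both share the M-step
# (least squares for fixed effects, moment updates for variances) and a
# final MAP pass that produces empirical-Bayes estimates, the Laplace
# marginal log-likelihood, and fixed-effect standard errors from the
# observed-information identity.

mlm_param_names <- c("alpha", "beta", "A", "b0", "b1", "dT")

#' Specify a multilevel cortisol response model
#'
#' @param parameters Curve parameters receiving fixed effects and random
#'   effects. Default `c("alpha", "beta", "A", "b0")`; add `"b1"` and/or
#'   `"dT"` for the six-parameter extended curve.
#' @param families Random-effect distribution family per parameter:
#'   `"lognormal"` (positivity-constrained; conventional for `alpha`,
#'   `beta`, `A`) or `"normal"` (`b0`, `b1`, `dT`).
#' @param covariates Named list mapping a parameter to covariate column
#'   names of the participant table, e.g.
#'   `list(A = "gender", b0 = c("gender", "dummy_control"))`. Covariates on
#'   log-normal parameters act multiplicatively on the natural scale.
#' @param fixed Named values for curve parameters excluded from
#'   `parameters` (default `b1 = 0`, `dT = 0`).
#' @param error_model Residual error model; only `"constant"` (a single
#'   additive SD) is implemented.
#' @param method `"saem"` (default, stochastic-approximation EM) or
#'   `"laplace"` (deterministic Laplace-EM; exact for models linear in the
#'   random effects and faster on large cohorts).
#' @param saem_burn,saem_total,mh_steps SAEM burn-in iterations (step size
#'   1), total iterations, and Metropolis sweeps per iteration.
#' @param max_iter,inner_iter,tol Laplace-EM iterations, Gauss-Newton
#'   steps per iteration, and relative convergence tolerance (also used by
#'   the final MAP pass).
#' @return Object of class `mlm_spec`.
#' @export
mlm_spec <- function(parameters = c("alpha", "beta", "A", "b0"),
                     families = c(alpha = "lognormal", beta = "lognormal",
                                  A = "lognormal", b0 = "normal",
                                  b1 = "normal", dT = "normal"),
                     covariates = list(),
                     fixed = list(b1 = 0, dT = 0),
                     error_model = "constant",
                     method = c("saem", "laplace"),
                     saem_burn = 300, saem_total = 600, mh_steps = 3,
                     max_iter = 40, inner_iter = 4, tol = 1e-5) {
  parameters <- match.arg(parameters, mlm_param_names, several.ok = TRUE)
  method <- match.arg(method)
  stopifnot(all(names(covariates) %in% mlm_param_names))
  if (!identical(error_model, "constant")) {
    stop("only the \"constant\" error model is implemented", call. = FALSE)
  }
  if (saem_total <= saem_burn) stop("`saem_total` must exceed `saem_burn`", call. = FALSE)
  drop_cov <- setdiff(names(covariates), parameters)
  if (length(drop_cov)) {
    warning("dropping covariate effects on parameters not in the model: ",
            paste(drop_cov, collapse = ", "))
    covariates <- covariates[setdiff(names(covariates), drop_cov)]
  }
  structure(list(parameters = parameters, families = families,
                 covariates = covariates, fixed = fixed,
                 error_model = error_model, method = method,
                 saem_burn = saem_burn, saem_total = saem_total,
                 mh_steps = mh_steps, max_iter = max_iter,
                 inner_iter = inner_iter, tol = tol),
            class = "mlm_spec")
}

#' Dummy coding of the acute stress test design
#'
#' Adds the four conventional dummy variables to a dataset:
#' `dummy_control` (any no-stress control condition), `dummy_gtsst`,
#' `dummy_secpt`, `dummy_mast`, leaving TSST-stress as the reference
#' category.
#'
#' @param data Long-format data frame with `condition` and `test_type`
#'   columns.
#' @return `data` with the four dummy columns appended.
#' @export
stress_test_dummies <- function(data) {
  ctrl <- !is.na(data$condition) & data$condition == "control"
  data$dummy_control <- as.numeric(ctrl)
  data$dummy_gtsst <- as.numeric(!ctrl & data$test_type == "gTSST")
  data$dummy_secpt <- as.numeric(!ctrl & data$test_type == "SECPT")
  data$dummy_mast <- as.numeric(!ctrl & data$test_type == "MAST")
  data
}

#' Retained covariate map for the full six-parameter model
#'
#' The retained covariate effects on the full acute-stress-test database:
#' gender on `A` and `b0`; the control-condition dummy on `A`, `b0`, `b1`
#' and `dT`; and the MAST dummy on `beta` and `b0`. The stress-test dummy
#' carrying the `beta`/`b0` effects is configurable because reasonable
#' readings of the source coding differ (MAST by default, SECPT as the
#' alternative).
#'
#' @param test_dummy Either `"mast"` (default) or `"secpt"`.
#' @return Named list suitable for the `covariates` argument of
#'   [mlm_spec()].
#' @export
default_covariate_map <- function(test_dummy = c("mast", "secpt")) {
  test_dummy <- match.arg(test_dummy)
  dcol <- paste0("dummy_", test_dummy)
  list(A = c("gender", "dummy_control"),
       b0 = c("gender", "dummy_control", dcol),
       b1 = "dummy_control",
       dT = "dummy_control",
       beta = dcol)
}

# --- internal machinery -----------------------------------------------------

# Evaluate the curve (and optionally its Jacobian w.r.t. phi) for all
# observations at once. `phi` is n_subj x P; `si` maps obs -> subject.
mlm_eval <- function(phi, si, t, p_names, log_scale, fixed_vals, jacobian = FALSE) {
  n_obs <- length(t)
  P <- length(p_names)
  psi <- phi
  if (any(log_scale)) psi[, log_scale] <- exp(phi[, log_scale, drop = FALSE])
  get_par <- function(nm) {
    if (nm %in% p_names) psi[si, match(nm, p_names)] else rep(fixed_vals[[nm]], n_obs)
  }
  alpha <- get_par("alpha"); beta <- get_par("beta"); A <- get_par("A")
  b0 <- get_par("b0"); b1 <- get_par("b1"); dT <- get_par("dT")
  x <- t - dT
  pos <- x > 0
  f <- numeric(n_obs)
  f[pos] <- stats::dgamma(x[pos], shape = alpha[pos], rate = beta[pos])
  g <- A * f + b0 + b1 * x
  if (!jacobian) return(list(g = g))
  J <- matrix(0, n_obs, P)
  lx <- numeric(n_obs); lx[pos] <- log(x[pos])
  for (k in seq_len(P)) {
    nm <- p_names[k]
    dk <- switch(nm,
      alpha = A * f * (log(beta) - digamma(alpha) + lx) * pos,
      beta = A * f * (alpha / beta - x) * pos,
      A = f,
      b0 = rep(1, n_obs),
      b1 = x,
      dT = {
        d <- -b1
        d[pos] <- d[pos] - A[pos] * f[pos] * ((alpha[pos] - 1) / x[pos] - beta[pos])
        d
      })
    if (log_scale[k]) dk <- dk * psi[si, k] # chain rule d psi / d phi
    J[, k] <- dk
  }
  list(g = g, J = J)
}

# Per-subject sums of squares / cross products of the Jacobian.
# Returns list with C (n x P x P array), Jr (n x P), rss (n).
mlm_accumulate <- function(J, r, si, n_subj) {
  P <- ncol(J)
  pairs <- which(upper.tri(diag(P), diag = TRUE), arr.ind = TRUE)
  M <- cbind(J[, pairs[, 1], drop = FALSE] * J[, pairs[, 2], drop = FALSE],
             J * r, r^2)
  agg <- rowsum(M, si, reorder = TRUE)
  full <- matrix(0, n_subj, ncol(M))
  full[as.integer(rownames(agg)), ] <- agg
  C <- array(0, c(n_subj, P, P))
  for (q in seq_len(nrow(pairs))) {
    C[, pairs[q, 1], pairs[q, 2]] <- full[, q]
    C[, pairs[q, 2], pairs[q, 1]] <- full[, q]
  }
  list(C = C, Jr = full[, nrow(pairs) + seq_len(P), drop = FALSE],
       rss = full[, ncol(M)])
}

# Penalized objective per subject (up to constants): rss/a2 + prior quad form
mlm_objective <- function(phi, M, omega_inv, rss_by_subj, a2) {
  dev <- phi - M
  rss_by_subj / a2 + rowSums(sweep(dev^2, 2, omega_inv, `*`))
}

mlm_rss_by_subj <- function(phi, si, t, y, p_names, log_scale, fixed_vals, n_subj) {
  g <- mlm_eval(phi, si, t, p_names, log_scale, fixed_vals)$g
  agg <- rowsum((y - g)^2, si, reorder = TRUE)
  out <- numeric(n_subj)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Fit the nonlinear multilevel model
#'
#' Maximizes the Laplace-approximate marginal likelihood of the
#' gamma-kernel response curve with per-subject random effects, optional
#' covariate effects on any curve parameter, and a constant residual error
#' model. One subject is one participant-condition series. Subjects with
#' fewer than 2 samples are excluded from fitting (recorded in
#' [exclusions()] of the returned object's `subjects` table attribute).
#'
#' @param data Baseline-corrected long-format data frame.
#' @param spec An [mlm_spec()].
#' @param pop Optional `population_curve` used to seed the fixed effects;
#'   by default a pooled curve is fitted internally for initialization.
#' @param seed Integer seed driving the SAEM Metropolis draws (default 1);
#'   the fit is exactly reproducible given the seed. Ignored by the
#'   deterministic `"laplace"` method.
#' @param verbose Print the EM trace.
#' @return Object of class `mlm_fit` with components `coefficients`
#'   (fixed-effect table with SE, Wald p and CV%), `omega` (random-effect
#'   variances on the transformed scale), `sigma` (residual SD), `psi`
#'   (per-subject empirical-Bayes curve parameters with MAE and bias),
#'   `logLik`, `bic`, and convergence information.
#' @export
fit_mlm <- function(data, spec = mlm_spec(), pop = NULL, seed = NULL,
                    verbose = FALSE) {
  check_long_data(data)
  cl <- match.call()
  data <- data[order(series_key(data), data$time_min), , drop = FALSE]
  key <- series_key(data)
  counts <- table(key)
  small <- names(counts)[counts < 2]
  excl <- NULL
  if (length(small)) {
    keep <- !(key %in% small)
    excl <- unique(data[!keep, intersect(c("participant_id", "condition"), names(data)),
                        drop = FALSE])
    excl$reason <- "fewer than 2 samples"
    data <- data[keep, , drop = FALSE]
    key <- key[keep]
  }
  subj_levels <- unique(key)
  n_subj <- length(subj_levels)
  if (n_subj < 2) stop("need at least 2 subjects with >= 2 samples", call. = FALSE)
  si <- match(key, subj_levels)
  t <- data$time_min
  y <- data$cortisol_nmol_l
  n_obs <- length(y)

  p_names <- spec$parameters
  P <- length(p_names)
  log_scale <- spec$families[p_names] == "lognormal"
  fixed_vals <- modifyList(list(alpha = 3, beta = 0.1, A = 0, b0 = 0, b1 = 0, dT = 0),
                           spec$fixed)

  # participant-level table (first row per subject)
  first <- match(subj_levels, key)
  subj <- data[first, setdiff(names(data), c("time_min", "cortisol_nmol_l")),
               drop = FALSE]
  rownames(subj) <- NULL

  # design matrices per parameter
  X <- lapply(p_names, function(p) {
    covs <- spec$covariates[[p]]
    if (is.null(covs) || length(covs) == 0) {
      matrix(1, n_subj, 1, dimnames = list(NULL, "(Intercept)"))
    } else {
      miss <- setdiff(covs, names(subj))
      if (length(miss)) stop("covariate column(s) not in data: ",
                             paste(miss, collapse = ", "), call. = FALSE)
      stats::model.matrix(stats::reformulate(covs), data = subj)
    }
  })
  names(X) <- p_names

  # --- initialization -------------------------------------------------------
  if (is.null(pop)) {
    pop <- tryCatch(fit_population_curve(data), error = function(e) NULL)
  }
  init_nat <- c(alpha = 3, beta = 0.1, A = 100, b0 = max(mean(y[t == 0]), 1),
                b1 = 0, dT = 0)
  if (!is.null(pop)) {
    pc <- coef(pop)
    init_nat[c("alpha", "beta", "b0")] <- pc[c("alpha", "beta", "b0")]
    init_nat["A"] <- max(pc["A"], 1)
  }
  mu0 <- vapply(seq_len(P), function(k) {
    v <- init_nat[[p_names[k]]]
    if (log_scale[k]) log(max(v, 1e-6)) else v
  }, numeric(1))
  theta <- lapply(seq_len(P), function(k) {
    th <- numeric(ncol(X[[k]]))
    th[1] <- mu0[k]
    th
  })
  M <- vapply(seq_len(P), function(k) drop(X[[k]] %*% theta[[k]]), numeric(n_subj))
  if (!is.matrix(M)) M <- matrix(M, nrow = n_subj)
  phi <- M
  # per-subject amplitude / baseline warm start
  if ("b0" %in% p_names) {
    base_obs <- rep(NA_real_, n_subj)
    at0 <- t == 0
    base_obs[si[at0]] <- y[at0]
    kb <- match("b0", p_names)
    phi[, kb] <- ifelse(is.na(base_obs), M[, kb], base_obs)
  }
  if ("A" %in% p_names && !is.null(pop)) {
    kA <- match("A", p_names)
    fpop <- gamma_density(t, init_nat[["alpha"]], init_nat[["beta"]])
    b_for_A <- if ("b0" %in% p_names) phi[si, match("b0", p_names)] else fixed_vals$b0
    num <- rowsum((y - b_for_A) * fpop, si, reorder = TRUE)
    den <- rowsum(fpop^2, si, reorder = TRUE)
    Ai <- rep(NA_real_, n_subj)
    idx <- as.integer(rownames(num))
    Ai[idx] <- num / pmax(den, 1e-12)
    phi[, kA] <- if (log_scale[kA]) {
      ifelse(is.na(Ai), M[, kA], log(pmax(Ai, 1)))
    } else {
      ifelse(is.na(Ai), M[, kA], Ai)
    }
  }
  # variance inits: spread of the warm-started modes where available,
  # conventional magnitudes otherwise
  omega <- vapply(seq_len(P), function(k) {
    v <- stats::var(phi[, k])
    if (!is.finite(v) || v < 1e-6) v <- if (log_scale[k]) 0.1 else 1
    v
  }, numeric(1))
  names(omega) <- p_names
  a2 <- {
    g0 <- mlm_eval(phi, si, t, p_names, log_scale, fixed_vals)$g
    max(mean((y - g0)^2), 1e-4)
  }

  omega_floor <- 1e-4
  trace <- NULL
  converged <- FALSE
  iter <- 0L

  # One vectorized damped Gauss-Newton pass over all subjects; returns the
  # updated modes, the per-subject damping, and the last accumulator.
  gn_pass <- function(phi, lambda, M, omega_inv, a2, n_steps) {
    obj <- mlm_objective(phi, M, omega_inv,
                         mlm_rss_by_subj(phi, si, t, y, p_names, log_scale,
                                         fixed_vals, n_subj), a2)
    acc <- NULL
    for (gn in seq_len(n_steps)) {
      ev <- mlm_eval(phi, si, t, p_names, log_scale, fixed_vals, jacobian = TRUE)
      acc <- mlm_accumulate(ev$J, y - ev$g, si, n_subj)
      phi_new <- phi
      for (i in seq_len(n_subj)) {
        H <- acc$C[i, , ] / a2 + diag(omega_inv, P) + diag(lambda[i], P)
        bvec <- acc$Jr[i, ] / a2 - omega_inv * (phi[i, ] - M[i, ])
        step <- tryCatch(solve(H, bvec), error = function(e) rep(0, P))
        phi_new[i, ] <- phi[i, ] + step
      }
      obj_new <- mlm_objective(phi_new, M, omega_inv,
                               mlm_rss_by_subj(phi_new, si, t, y, p_names,
                                               log_scale, fixed_vals, n_subj),
                               a2)
      accept <- is.finite(obj_new) & obj_new <= obj + 1e-10
      phi[accept, ] <- phi_new[accept, ]
      lambda[accept] <- pmax(lambda[accept] / 3, 1e-9)
      lambda[!accept] <- pmin(lambda[!accept] * 8, 1e6)
      obj[accept] <- obj_new[accept]
    }
    list(phi = phi, lambda = lambda, obj = obj)
  }

  refresh_M <- function(theta) {
    M <- vapply(seq_len(P), function(k) drop(X[[k]] %*% theta[[k]]), numeric(n_subj))
    if (!is.matrix(M)) M <- matrix(M, nrow = n_subj)
    M
  }

  if (spec$method == "saem") {
    # ---- SAEM: Metropolis E-step + stochastic-approximation M-step ----
    if (is.null(seed)) seed <- 1L
    with_seed(seed, {
      cscale <- 2.38 / sqrt(P) # standard multivariate random-walk scaling
      rss_cur <- mlm_rss_by_subj(phi, si, t, y, p_names, log_scale,
                                 fixed_vals, n_subj)
      m_s <- phi
      v_s <- phi^2
      rss_s <- sum(rss_cur)
      Larr <- NULL # per-subject Cholesky of the Laplace posterior covariance
      refresh_L <- function(phi, a2, omega) {
        ev <- mlm_eval(phi, si, t, p_names, log_scale, fixed_vals, jacobian = TRUE)
        acc <- mlm_accumulate(ev$J, y - ev$g, si, n_subj)
        L <- array(0, c(n_subj, P, P))
        oi <- diag(1 / omega, P)
        for (i in seq_len(n_subj)) {
          S <- tryCatch(solve(acc$C[i, , ] / a2 + oi), error = function(e) diag(omega, P))
          cS <- tryCatch(t(chol(S)), error = function(e) diag(sqrt(omega), P))
          L[i, , ] <- cS
        }
        L
      }
      prior_quad <- function(phi) {
        rowSums(sweep((phi - M)^2, 2, 1 / omega, `*`))
      }
      pq_cur <- prior_quad(phi)
      for (k_it in seq_len(spec$saem_total)) {
        if (k_it %% 25 == 1) Larr <- refresh_L(phi, a2, omega)
        for (sweep_i in seq_len(spec$mh_steps)) {
          eps <- matrix(rnorm(n_subj * P), n_subj, P)
          delta <- matrix(0, n_subj, P)
          for (p in seq_len(P)) for (q in seq_len(p)) {
            delta[, p] <- delta[, p] + Larr[, p, q] * eps[, q]
          }
          prop <- phi + cscale * delta
          rss_prop <- mlm_rss_by_subj(prop, si, t, y, p_names, log_scale,
                                      fixed_vals, n_subj)
          pq_prop <- prior_quad(prop)
          logr <- (rss_cur - rss_prop) / (2 * a2) + (pq_cur - pq_prop) / 2
          acc_i <- log(runif(n_subj)) < logr
          phi[acc_i, ] <- prop[acc_i, , drop = FALSE]
          rss_cur[acc_i] <- rss_prop[acc_i]
          pq_cur[acc_i] <- pq_prop[acc_i]
          if (k_it <= spec$saem_burn) {
            cscale <- cscale * exp(0.4 * (mean(acc_i) - 0.25))
          }
        }
        gamma_k <- if (k_it <= spec$saem_burn) 1 else 1 / (k_it - spec$saem_burn)
        m_s <- m_s + gamma_k * (phi - m_s)
        v_s <- v_s + gamma_k * (phi^2 - v_s)
        rss_s <- rss_s + gamma_k * (sum(rss_cur) - rss_s)
        for (k in seq_len(P)) theta[[k]] <- qr.solve(X[[k]], m_s[, k])
        M_new <- refresh_M(theta)
        pq_cur <- pq_cur + rowSums(sweep((phi - M_new)^2 - (phi - M)^2, 2,
                                         1 / omega, `*`))
        M <- M_new
        omega_new <- pmax(colMeans(v_s - 2 * m_s * M + M^2), omega_floor)
        pq_cur <- rowSums(sweep((phi - M)^2, 2, 1 / omega_new, `*`))
        omega <- omega_new
        a2 <- max(rss_s / n_obs, 1e-8)
        if (verbose && k_it %% 50 == 0) {
          message(sprintf("SAEM iter %d: a = %.4f, MH scale %.2f", k_it,
                          sqrt(a2), cscale))
        }
      }
      iter <- spec$saem_total
      converged <- TRUE
    })
  } else {
    # ---- deterministic Laplace-EM ----
    lambda <- rep(1e-3, n_subj)
    for (iter in seq_len(spec$max_iter)) {
      old <- c(unlist(theta), omega, a2)
      omega_inv <- 1 / omega
      gp <- gn_pass(phi, lambda, M, omega_inv, a2, spec$inner_iter)
      phi <- gp$phi; lambda <- gp$lambda
      ev <- mlm_eval(phi, si, t, p_names, log_scale, fixed_vals, jacobian = TRUE)
      acc <- mlm_accumulate(ev$J, y - ev$g, si, n_subj)
      Spp <- matrix(0, n_subj, P)
      corr <- numeric(n_subj)
      for (i in seq_len(n_subj)) {
        H <- acc$C[i, , ] / a2 + diag(omega_inv, P)
        S <- tryCatch(solve(H), error = function(e) diag(omega, P))
        Spp[i, ] <- diag(S)
        corr[i] <- sum(acc$C[i, , ] * S)
      }
      for (k in seq_len(P)) theta[[k]] <- qr.solve(X[[k]], phi[, k])
      M <- refresh_M(theta)
      omega <- pmax(colMeans((phi - M)^2 + Spp), omega_floor)
      a2 <- max((sum(acc$rss) + sum(corr)) / n_obs, 1e-8)
      new <- c(unlist(theta), omega, a2)
      delta <- max(abs(new - old) / (1 + abs(old)))
      if (verbose) {
        message(sprintf("EM iter %d: a = %.4f, delta = %.2e", iter, sqrt(a2), delta))
      }
      trace <- c(trace, delta)
      if (delta < spec$tol) { converged <- TRUE; break }
    }
    if (!converged && utils::tail(trace, 1) > 1e-2) {
      stop("multilevel fit did not converge after ", spec$max_iter,
           " iterations (last relative change ", format(utils::tail(trace, 1)),
           ")", call. = FALSE)
    }
  }

  # ----- final MAP pass and Laplace quantities ------------------------------
  omega_inv <- 1 / omega
  gp <- gn_pass(phi, rep(1e-3, n_subj), M, omega_inv, a2, 8)
  phi <- gp$phi
  ev <- mlm_eval(phi, si, t, p_names, log_scale, fixed_vals, jacobian = TRUE)
  r <- y - ev$g
  acc <- mlm_accumulate(ev$J, r, si, n_subj)
  n_i <- tabulate(si, n_subj)
  Spp <- matrix(0, n_subj, P)
  S_list <- vector("list", n_subj)
  logdetH <- numeric(n_subj)
  for (i in seq_len(n_subj)) {
    H <- acc$C[i, , ] / a2 + diag(omega_inv, P)
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) {
      logdetH[i] <- sum(log(omega_inv))
      S_list[[i]] <- diag(omega, P)
    } else {
      logdetH[i] <- 2 * sum(log(diag(ch)))
      S_list[[i]] <- chol2inv(ch)
    }
    Spp[i, ] <- diag(S_list[[i]])
  }
  names(omega) <- p_names
  dev <- phi - M
  ll <- sum(-acc$rss / (2 * a2) - n_i / 2 * log(2 * pi * a2) -
              rowSums(sweep(dev^2, 2, omega_inv, `*`)) / 2 -
              sum(log(2 * pi * omega)) / 2 + P / 2 * log(2 * pi) - logdetH / 2)
  k_par <- sum(vapply(X, ncol, integer(1))) + P + 1
  bic <- k_par * log(n_obs) - 2 * ll

  # fixed-effect SEs: joint observed information over all coefficient
  # blocks, I = sum_i B_i' (Omega^-1 - Omega^-1 S_i Omega^-1) B_i
  q_p <- vapply(X, ncol, integer(1))
  q_tot <- sum(q_p)
  offs <- c(0, cumsum(q_p))[seq_len(P)]
  info <- matrix(0, q_tot, q_tot)
  Oinv <- diag(omega_inv, P)
  for (i in seq_len(n_subj)) {
    W <- Oinv - Oinv %*% S_list[[i]] %*% Oinv
    B <- matrix(0, P, q_tot)
    for (k in seq_len(P)) B[k, offs[k] + seq_len(q_p[k])] <- X[[k]][i, ]
    info <- info + crossprod(B, W %*% B)
  }
  V <- tryCatch(solve(info), error = function(e) matrix(NA_real_, q_tot, q_tot))
  se_all <- sqrt(pmax(diag(V), 0))
  coefs <- do.call(rbind, lapply(seq_len(P), function(k) {
    est <- theta[[k]]
    se <- se_all[offs[k] + seq_len(q_p[k])]
    data.frame(parameter = p_names[k], term = colnames(X[[k]]),
               estimate = est, se = se,
               z = est / se, p = 2 * stats::pnorm(-abs(est / se)),
               cv_pct = 100 * se / abs(est), stringsAsFactors = FALSE)
  }))
  rownames(coefs) <- paste(coefs$parameter, coefs$term, sep = ".")

  # empirical-Bayes curve parameters per subject, MAE/bias
  psi_mat <- phi
  psi_mat[, log_scale] <- exp(phi[, log_scale, drop = FALSE])
  colnames(psi_mat) <- p_names
  abs_err <- rowsum(abs(r), si, reorder = TRUE)
  bias_s <- rowsum(r, si, reorder = TRUE)
  psi <- data.frame(subj[, intersect(c("participant_id", "condition", "study_id",
                                       "gender", "test_type"), names(subj)),
                         drop = FALSE],
                    psi_mat, n_obs = n_i,
                    mae = as.numeric(abs_err) / n_i,
                    bias = as.numeric(bias_s) / n_i,
                    stringsAsFactors = FALSE)
  for (nm in setdiff(mlm_param_names, p_names)) psi[[nm]] <- fixed_vals[[nm]]

  fit <- structure(list(
    spec = spec, coefficients = coefs, theta = theta, omega = omega,
    sigma = sqrt(a2), phi = phi, phi_mean = M, Spp = Spp, psi = psi,
    design = X, logLik = ll, bic = bic, n_obs = n_obs, n_subjects = n_subj,
    iterations = iter, converged = converged, exclusions = excl,
    data = data.frame(key = key, time_min = t, cortisol_nmol_l = y,
                      fitted = ev$g, stringsAsFactors = FALSE),
    call = cl
  ), class = "mlm_fit")
  fit
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("Nonlinear multilevel model of the cortisol response\n")
  cat(sprintf("  %d subjects, %d observations; parameters: %s\n",
              x$n_subjects, x$n_obs, paste(x$spec$parameters, collapse = ", ")))
  cat(sprintf("  residual SD a = %.3f nmol/L; logLik = %.1f; BIC = %.1f (%s in %d EM iterations)\n",
              x$sigma, x$logLik, x$bic,
              if (x$converged) "converged" else "max iterations reached",
              x$iterations))
  invisible(x)
}

#' @export
summary.mlm_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients, omega = object$omega,
              sigma = object$sigma, bic = object$bic, logLik = object$logLik,
              n_subjects = object$n_subjects, n_obs = object$n_obs,
              mae = mean(object$psi$mae), bias = mean(object$psi$bias))
  class(out) <- "summary.mlm_fit"
  out
}

#' @export
print.summary.mlm_fit <- function(x, ...) {
  cat("Fixed effects (transformed scale; log for alpha, beta, A):\n")
  print(cbind(round(x$coefficients[, c("estimate", "se", "z")], 4),
              p = signif(x$coefficients$p, 3),
              `CV%` = round(x$coefficients$cv_pct, 1)))
  cat("\nRandom-effect variances (transformed scale):\n")
  print(round(x$omega, 4))
  cat(sprintf("\nResidual SD: %.3f nmol/L; mean per-subject MAE %.3f, bias %.3f\n",
              x$sigma, x$mae, x$bias))
  cat(sprintf("logLik %.1f, BIC %.1f (%d subjects, %d observations)\n",
              x$logLik, x$bic, x$n_subjects, x$n_obs))
  invisible(x)
}

#' @export
coef.mlm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, rownames(object$coefficients))
}

#' @export
logLik.mlm_fit <- function(object, ...) {
  structure(object$logLik,
            df = nrow(object$coefficients) + length(object$omega) + 1,
            nobs = object$n_obs, class = "logLik")
}

mlm_subject_index <- function(object, participant_id, condition = NULL) {
  p <- object$psi
  idx <- which(p$participant_id == as.character(participant_id))
  if (!is.null(condition) && "condition" %in% names(p)) {
    idx <- idx[p$condition[idx] == condition]
  }
  if (length(idx) == 0) stop("unknown participant_id", call. = FALSE)
  idx[1]
}

#' Empirical-Bayes response curve of one participant
#'
#' @param object An `mlm_fit`.
#' @param participant_id Participant to extract.
#' @param condition Optional condition when a participant has several
#'   series.
#' @return A [response_curve()] with the participant's shrunken parameter
#'   estimates.
#' @export
predict_individual <- function(object, participant_id, condition = NULL) {
  stopifnot(inherits(object, "mlm_fit"))
  i <- mlm_subject_index(object, participant_id, condition)
  p <- object$psi
  response_curve(p$alpha[i], p$beta[i], A = p$A[i], b0 = p$b0[i],
                 b1 = p$b1[i], dT = p$dT[i])
}

#' @export
predict.mlm_fit <- function(object, participant_id = NULL,
                            times = time_grid(0, 80), condition = NULL, ...) {
  p <- object$psi
  idx <- if (is.null(participant_id)) seq_len(nrow(p)) else
    vapply(participant_id, mlm_subject_index, integer(1), object = object,
           condition = condition)
  res <- vapply(idx, function(i) {
    eval_curve(response_curve(p$alpha[i], p$beta[i], A = p$A[i], b0 = p$b0[i],
                              b1 = p$b1[i], dT = p$dT[i]), times)
  }, numeric(length(times)))
  out <- if (length(times) == 1) matrix(res, ncol = 1) else t(res)
  rownames(out) <- p$participant_id[idx]
  colnames(out) <- times
  out
}

#' @export
residuals.mlm_fit <- function(object, ...) {
  object$data$cortisol_nmol_l - object$data$fitted
}

#' @export
fitted.mlm_fit <- function(object, ...) object$data$fitted

#' @export
plot.mlm_fit <- function(x, n_show = 12, ...) {
  p <- x$psi
  idx <- head(order(p$n_obs, decreasing = TRUE), n_show)
  grid <- time_grid(0, 80, 1)
  pred <- predict(x, times = grid)[idx, , drop = FALSE]
  matplot(grid, t(pred), type = "l", lty = 1,
          col = adjustcolor("steelblue", 0.6),
          xlab = "Time since stressor onset (min)",
          ylab = "Cortisol (nmol/L)",
          main = "Empirical-Bayes individual response curves", ...)
  invisible(x)
}

#' Simulate response data from a fitted multilevel model
#'
#' Draws new subjects from the fitted population distribution and new
#' observations with the fitted residual SD at the requested times.
#'
#' @param object An `mlm_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Integer seed.
#' @param times Sampling times in minutes (default the fit's observed
#'   design, per subject).
#' @param ... Unused.
#' @return A list of `nsim` long-format data frames.
#' @export
simulate.mlm_fit <- function(object, nsim = 1, seed = NULL,
                             times = c(0, 15, 25, 40, 60, 80), ...) {
  p_names <- object$spec$parameters
  log_scale <- object$spec$families[p_names] == "lognormal"
  n <- object$n_subjects
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      phi <- object$phi_mean +
        matrix(rnorm(n * length(p_names)), n) %*% diag(sqrt(object$omega), length(p_names))
      psi <- phi
      psi[, log_scale] <- exp(phi[, log_scale, drop = FALSE])
      colnames(psi) <- p_names
      full <- modifyList(list(alpha = 3, beta = 0.1, A = 0, b0 = 0, b1 = 0, dT = 0),
                         object$spec$fixed)
      do.call(rbind, lapply(seq_len(n), function(i) {
        pars <- full
        for (k in seq_along(p_names)) pars[[p_names[k]]] <- psi[i, k]
        crv <- response_curve(pars$alpha, pars$beta, pars$A, pars$b0,
                              pars$b1, pars$dT)
        data.frame(participant_id = sprintf("sim%04d", i),
                   time_min = times,
                   cortisol_nmol_l = eval_curve(crv, times) +
                     rnorm(length(times), 0, object$sigma),
                   stringsAsFactors = FALSE)
      }))
    })
  })
}

#' Simulate a hierarchical cohort from explicit population values
#'
#' Generates long-format data directly from the multilevel model's
#' data-generating process: per-subject transformed-scale parameters drawn
#' from `N(mu + covariate effects, omega)`, curve evaluation at `times`,
#' plus white residual noise. Useful for parameter-recovery studies.
#'
#' @param n Number of subjects.
#' @param times Sampling times (minutes).
#' @param mu Named vector of transformed-scale population means, e.g.
#'   `c(alpha = log(3), beta = log(0.1), A = log(150), b0 = 5)`.
#' @param omega Named vector of random-effect variances (same names).
#' @param sigma Residual SD in nmol/L.
#' @param families Distribution family per parameter (as in [mlm_spec()]).
#' @param covariate_effects Optional named list
#'   `parameter -> c(genderM = effect)` applied on the transformed scale to
#'   male subjects (gender is assigned half/half).
#' @param seed Integer seed.
#' @return Long-format data frame with a `gender` column and attribute
#'   `truth` (per-subject natural-scale parameters).
#' @export
simulate_mlm_cohort <- function(n, times, mu, omega, sigma,
                                families = c(alpha = "lognormal", beta = "lognormal",
                                             A = "lognormal", b0 = "normal",
                                             b1 = "normal", dT = "normal"),
                                covariate_effects = NULL, seed = 1) {
  p_names <- names(mu)
  with_seed(seed, {
    gender <- sample(rep(c("F", "M"), length.out = n))
    phi <- sapply(p_names, function(p) {
      eff <- if (!is.null(covariate_effects[[p]])) {
        covariate_effects[[p]][["genderM"]] * (gender == "M")
      } else 0
      rnorm(n, mu[[p]] + eff, sqrt(omega[[p]]))
    })
    if (!is.matrix(phi)) phi <- matrix(phi, nrow = n, dimnames = list(NULL, p_names))
    psi <- phi
    for (p in p_names) if (families[[p]] == "lognormal") psi[, p] <- exp(phi[, p])
    truth <- data.frame(participant_id = sprintf("sim%04d", seq_len(n)),
                        gender = gender, psi, stringsAsFactors = FALSE)
    full_default <- list(alpha = 3, beta = 0.1, A = 0, b0 = 0, b1 = 0, dT = 0)
    data <- do.call(rbind, lapply(seq_len(n), function(i) {
      pars <- full_default
      for (p in p_names) pars[[p]] <- psi[i, p]
      crv <- response_curve(pars$alpha, pars$beta, pars$A, pars$b0, pars$b1, pars$dT)
      data.frame(participant_id = truth$participant_id[i],
                 study_id = "simstudy", condition = "stress",
                 gender = gender[i], test_type = "TSST",
                 time_min = times,
                 cortisol_nmol_l = eval_curve(crv, times) + rnorm(length(times), 0, sigma),
                 stringsAsFactors = FALSE)
    }))
    attr(data, "truth") <- truth
    data
  })
}

#' Decide whether a covariate effect is retained
#'
#' A covariate effect is kept only when its Wald p-value is below 5%, its
#' coefficient of variation (100 * SE / |estimate|) is at most 25%, and
#' adding it does not increase the BIC relative to the nested fit without
#' it.
#'
#' @param fit_with,fit_without Nested `mlm_fit` objects on identical data.
#' @param coefficient Row name of the tested coefficient in
#'   `fit_with$coefficients` (e.g. `"A.genderM"`).
#' @param p_threshold,cv_threshold Retention thresholds.
#' @return List with `retain` (logical) and the underlying `p`, `cv_pct`
#'   and `delta_bic`.
#' @export
evaluate_covariate <- function(fit_with, fit_without, coefficient,
                               p_threshold = 0.05, cv_threshold = 25) {
  stopifnot(inherits(fit_with, "mlm_fit"), inherits(fit_without, "mlm_fit"))
  if (fit_with$n_obs != fit_without$n_obs ||
      fit_with$n_subjects != fit_without$n_subjects) {
    stop("fits are not nested on identical data", call. = FALSE)
  }
  if (nrow(fit_with$coefficients) <= nrow(fit_without$coefficients) - 1) {
    stop("`fit_with` must extend `fit_without`", call. = FALSE)
  }
  co <- fit_with$coefficients[coefficient, ]
  if (nrow(co) == 0 || is.na(co$estimate)) stop("unknown coefficient: ", coefficient,
                                                call. = FALSE)
  delta_bic <- fit_with$bic - fit_without$bic
  list(retain = co$p < p_threshold && co$cv_pct <= cv_threshold && delta_bic <= 0,
       p = co$p, cv_pct = co$cv_pct, delta_bic = delta_bic)
}
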
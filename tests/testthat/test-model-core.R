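test_that("conditional response probability follows the logistic sub-model", {
  p <- jm_params(alpha_z = -1.8, alpha_m = 0.3, lambda = 1, beta_z = 0,
                 beta_m = 0, sigma_b = 1)
  rec <- one_record(1, 1, 1, z = 1, tmb = 2)
  # alpha_z'Z + alpha_m TMB = -1.2; independent closed form 1/(1 + e^1.2)
  expect_equal(response_probability(p, rec, b = 0), 1 / (1 + exp(1.2)),
               tolerance = 1e-12)
  expect_equal(response_probability(p, rec, b = 1.2), 0.5, tolerance = 1e-12)
  expect_equal(response_probability(p, rec, b = 60), 1, tolerance = 1e-10)
  expect_equal(response_probability(p, rec, b = -60), 0, tolerance = 1e-10)
  # strictly increasing in b
  bs <- seq(-3, 3, by = 0.5)
  pr <- vapply(bs, function(b) response_probability(p, rec, b), numeric(1))
  expect_true(all(diff(pr) > 0))
})

test_that("conditional hazard and survival follow the Weibull-PH sub-model", {
  p <- jm_params(alpha_z = 0, alpha_m = 0, lambda = 1, beta_z = 0,
                 beta_m = 0, sigma_b = 1)
  rec <- one_record(1, 1, 1, z = 0, tmb = 0)
  hs <- hazard_survival(p, rec, b = 0)
  # unit exponential: h = 1, S(1) = e^-1
  expect_equal(hs$hazard, 1, tolerance = 1e-12)
  expect_equal(hs$survival, exp(-1), tolerance = 1e-12)
  expect_equal(hs$cumhaz0, 1, tolerance = 1e-12)
  # S -> 1 as T -> 0+, and S nonincreasing in T
  p2 <- jm_params(alpha_z = 0.5, alpha_m = 0.1, lambda = 1.7, beta_z = -0.8,
                  beta_m = 0.2, sigma_b = 1)
  ts <- c(1e-9, 0.1, 0.5, 1, 2, 5)
  Ss <- vapply(ts, function(tt)
    hazard_survival(p2, one_record(1, tt, 1, z = 1, tmb = 0.7),
                    b = 0.3)$survival, numeric(1))
  expect_equal(Ss[1], 1, tolerance = 1e-6)
  expect_true(all(diff(Ss) < 0))
})

test_that("random-effect mode matches a dense grid search and its curvature
           matches numerical second differences", {
  p <- jm_params(alpha_z = 0, alpha_m = 0, lambda = 1, beta_z = 0,
                 beta_m = 0, sigma_b = 1)
  rec <- one_record(1, 1, 1, z = 0, tmb = 0)
  m <- random_effect_mode(p, rec, "true")
  expect_true(m$converged)
  expect_equal(m$mode, grid_mode_oracle(p, rec, "true"), tolerance = 2e-6)

  # randomized records: mode via grid, curvature via central differences
  set.seed(8)
  for (i in 1:8) {
    pars <- jm_params(alpha_z = rnorm(1), alpha_m = rnorm(1, 0, 0.4),
                      lambda = runif(1, 0.6, 1.8), beta_z = rnorm(1),
                      beta_m = rnorm(1, 0, 0.4), sigma_b = runif(1, 0.3, 1.4))
    rec <- one_record(rbinom(1, 1, 0.5), runif(1, 0.2, 4), rbinom(1, 1, 0.8),
                      z = rbinom(1, 1, 0.5), tmb = rnorm(1, 0, 1.4))
    m <- random_effect_mode(pars, rec, "true")
    expect_true(m$converged)
    expect_equal(m$mode, grid_mode_oracle(pars, rec, "true"),
                 tolerance = 5e-6)
    kfun <- kernel_fun(pars, rec, "true")
    h <- 1e-4
    k2 <- (log(kfun(m$mode + h)) - 2 * log(kfun(m$mode)) +
             log(kfun(m$mode - h))) / h^2
    expect_equal(m$curvature, -k2, tolerance = 1e-5)
  }

  # sigma_b -> 0: the prior term dominates and the mode collapses to 0
  p0 <- jm_params(alpha_z = 0.5, alpha_m = 0.2, lambda = 1, beta_z = 1,
                  beta_m = -0.3, sigma_b = 1e-5)
  rec <- one_record(1, 2, 1, z = 1, tmb = 1)
  expect_lt(abs(random_effect_mode(p0, rec, "true")$mode), 1e-6)
})

test_that("Laplace marginal log-likelihood agrees with adaptive quadrature,
           is additive over patients, and degenerates as sigma_b -> 0", {
  set.seed(21)
  # 50 random single-record cases with sigma_b in [0.2, 1.5]
  rel_err <- replicate(50, {
    pars <- jm_params(alpha_z = rnorm(1), alpha_m = rnorm(1, 0, 0.4),
                      lambda = runif(1, 0.6, 1.8), beta_z = rnorm(1),
                      beta_m = rnorm(1, 0, 0.4),
                      sigma_b = runif(1, 0.2, 1.5))
    rec <- one_record(rbinom(1, 1, 0.5), runif(1, 0.2, 4),
                      rbinom(1, 1, 0.8), z = rbinom(1, 1, 0.5),
                      tmb = rnorm(1, 0, 1.4))
    lap <- exp(laplace_loglik(pars, rec, "true"))
    quad <- quad_marginal(pars, rec, "true")
    abs(lap - quad) / quad
  })
  expect_lt(max(rel_err), 0.02)

  # additivity over independent patients
  p <- default_truth()
  co <- small_cohort(n = 9, seed = 4)
  a <- jointTMB:::.jm_subset(co, 1:4)
  b <- jointTMB:::.jm_subset(co, 5:9)
  expect_equal(laplace_loglik(p, co, "true"),
               laplace_loglik(p, a, "true") + laplace_loglik(p, b, "true"),
               tolerance = 1e-10)

  # sigma_b -> 0: separate-model log-likelihood at b = 0
  p0 <- jm_params(alpha_z = -1.8, alpha_m = 0.3, lambda = 1.0, beta_z = 2.2,
                  beta_m = -0.4, sigma_b = 1e-6)
  sep <- sum(vapply(seq_len(length(co)), function(i) {
    rec <- jointTMB:::.jm_subset(co, i)
    f0 <- kernel_fun(p0, rec, "true")
    log(f0(0) / dnorm(0, sd = p0$sigma_b))
  }, numeric(1)))
  expect_equal(laplace_loglik(p0, co, "true"), sep, tolerance = 1e-6)
})

test_that("analytic joint score equals the numeric gradient of the Laplace
           objective", {
  set.seed(5)
  co <- small_cohort(n = 20, seed = 5)
  for (pars in list(default_truth(),
                    jm_params(-1, 0.1, 1.3, 1.5, -0.2, 0.7),
                    jm_params(0.4, -0.25, 0.8, -0.9, 0.35, 1.2))) {
    sc <- joint_score(pars, co, "true")
    ng <- num_grad(function(th)
      laplace_loglik(jm_from_theta(th, 1), co, "true"), jm_theta(pars))
    expect_lt(max(abs(sc - ng) / (1 + abs(ng))), 1e-4)
  }
})

test_that("with tiny fixed sigma_b the score blocks match the separate
           logistic and Weibull-PH scores", {
  co <- small_cohort(n = 40, seed = 9)
  pars <- jm_params(alpha_z = -1.2, alpha_m = 0.25, lambda = 1.1,
                    beta_z = 1.8, beta_m = -0.3, sigma_b = 1e-4)
  sc <- joint_score(pars, co, "true")
  x <- co$tmb_true
  # separate logistic score: X'(R - F)
  etaR <- co$Z[, 1] * pars$alpha_z + pars$alpha_m * x
  resid <- co$response - plogis(etaR)
  expect_lt(max(abs(c(sum(resid * co$Z[, 1]), sum(resid * x)) -
                      sc[c("alpha_z1", "alpha_m")])), 1e-3)
  # separate Weibull-PH score
  etaT <- co$Z[, 1] * pars$beta_z + pars$beta_m * x
  G <- co$time^pars$lambda * exp(etaT)
  expect_lt(abs(sum(co$event * (1 / pars$lambda + log(co$time)) -
                      G * log(co$time)) - sc["lambda"]), 1e-3)
  expect_lt(max(abs(c(sum((co$event - G) * co$Z[, 1]),
                      sum((co$event - G) * x)) -
                      sc[c("beta_z1", "beta_m")])), 1e-3)
})

test_that("joint fitting reaches a fixed point with a small score norm and
           rejects degenerate cohorts", {
  co <- small_cohort(n = 120, seed = 12)
  fit <- fit_joint(co, "true")
  expect_true(fit$converged)
  expect_lt(fit$score_norm_at_optimum, 1e-6)
  expect_equal(fit$estimator_tag, "true_data")
  expect_true(all(is.finite(fit$std_errors)))
  expect_equal(fit$std_errors, sqrt(diag(fit$covariance)))
  expect_true(all(fit$random_effects$converged))
  # refitting from the optimum moves nothing materially
  fit2 <- fit_joint(co, "true", init = fit$estimates)
  expect_lt(max(abs(jm_theta(fit2$estimates) - jm_theta(fit$estimates))),
            1e-5)
  # degenerate inputs
  co_all1 <- co; co_all1$response <- rep(1, length(co))
  expect_error(fit_joint(co_all1, "true"), "response classes")
  co_cens <- co; co_cens$event <- rep(0, length(co))
  expect_error(fit_joint(co_cens, "true"), "event")
  expect_error(fit_joint(jointTMB:::.jm_subset(co, 1:4), "true"), "fewer")
})

test_that("as sigma_b -> 0 the joint fit reproduces the separate fits", {
  # data generated with essentially no shared random effect
  pars <- jm_params(alpha_z = -1.0, alpha_m = 0.3, lambda = 1.0,
                    beta_z = 1.5, beta_m = -0.4, sigma_b = 0.01)
  co <- simulate_cohort(sim_config(n_patients = 300, params = pars), 31)
  jf <- fit_joint(co, "true", sigma_b_fixed = 0.01)
  lg <- fit_separate_logistic(co, "true")
  wb <- fit_separate_weibull_ph(co, "true")
  th <- jm_theta(jf$estimates)
  expect_lt(abs(th["alpha_z1"] - lg$estimates["alpha_z1"]),
            2 * lg$std_errors["alpha_z1"])
  expect_lt(abs(th["alpha_m"] - lg$estimates["alpha_m"]),
            2 * lg$std_errors["alpha_m"])
  expect_lt(abs(th["lambda"] - wb$estimates["lambda"]),
            2 * wb$std_errors["lambda"])
  expect_lt(abs(th["beta_m"] - wb$estimates["beta_m"]),
            2 * wb$std_errors["beta_m"])
})
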
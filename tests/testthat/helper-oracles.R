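# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately implemented by brute force (grids, quadrature,
# pair counting, hand formulas) so they stay independent of the package's
# own computational paths.

default_truth <- function() {
  jm_params(alpha_z = -1.8, alpha_m = 0.3, lambda = 1.0,
            beta_z = 2.2, beta_m = -0.4, sigma_b = 1.0)
}

small_cohort <- function(n = 30, seed = 1, params = default_truth()) {
  simulate_cohort(sim_config(n_patients = n, params = params), seed)
}

one_record <- function(response, time, event, z, tmb) {
  jm_cohort(response = response, time = time, event = event, Z = z,
            tmb_obs = tmb, tmb_true = tmb)
}

# central-difference gradient of a scalar function
num_grad <- function(f, x, h_scale = 1e-5) {
  vapply(seq_along(x), function(j) {
    h <- h_scale * (1 + abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# per-patient joint density kernel exp{k(b)} evaluated directly from the
# model definition (not via package internals)
kernel_fun <- function(params, rec, tmb_source) {
  x <- if (tmb_source == "true") rec$tmb_true[1] else rec$tmb_obs[1]
  z <- rec$Z[1, ]
  etaR0 <- sum(z * params$alpha_z) + params$alpha_m * x
  etaT0 <- sum(z * params$beta_z) + params$beta_m * x
  R <- rec$response[1]; Tt <- rec$time[1]; D <- rec$event[1]
  function(b) {
    pr <- plogis(etaR0 + b)
    lik_R <- pr^R * (1 - pr)^(1 - R)
    h <- params$lambda * Tt^(params$lambda - 1) * exp(etaT0 + b)
    S <- exp(-Tt^params$lambda * exp(etaT0 + b))
    lik_T <- h^D * S
    lik_R * lik_T * dnorm(b, sd = params$sigma_b)
  }
}

# two-stage dense grid argmax of log kernel (mode oracle)
grid_mode_oracle <- function(params, rec, tmb_source, lims = c(-10, 10)) {
  f <- kernel_fun(params, rec, tmb_source)
  g <- function(b) log(f(b))
  bs <- seq(lims[1], lims[2], by = 1e-3)
  b0 <- bs[which.max(g(bs))]
  bs <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-6)
  bs[which.max(g(bs))]
}

# adaptive-quadrature marginal likelihood of one record
quad_marginal <- function(params, rec, tmb_source) {
  f <- kernel_fun(params, rec, tmb_source)
  lim <- 8 * max(params$sigma_b, 1)
  stats::integrate(f, -lim, lim, rel.tol = 1e-10)$value
}

# adaptive-quadrature joint prognosis probability p(R = 1, T > T0)
quad_prognosis <- function(params, rec, horizon, tmb_source) {
  x <- if (tmb_source == "true") rec$tmb_true[1] else rec$tmb_obs[1]
  z <- rec$Z[1, ]
  etaR0 <- sum(z * params$alpha_z) + params$alpha_m * x
  etaT0 <- sum(z * params$beta_z) + params$beta_m * x
  f <- function(b)
    plogis(etaR0 + b) * exp(-horizon^params$lambda * exp(etaT0 + b)) *
      dnorm(b, sd = params$sigma_b)
  lim <- 8 * max(params$sigma_b, 1)
  stats::integrate(f, -lim, lim, rel.tol = 1e-10)$value
}

# exhaustive pair-counting AUC (ties count 1/2)
auc_pairs <- function(tmb, labels) {
  pos <- tmb[labels == 1]
  neg <- tmb[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# hand Kaplan-Meier median: smallest event time with S(t) <= 0.5
km_median_hand <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  S <- 1
  at_risk <- length(time)
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      S <- S * (1 - 1 / at_risk)
      if (S <= 0.5 + 1e-12) return(time[i])
    }
    at_risk <- at_risk - 1
  }
  Inf
}

# hand two-group log-rank statistic (observed minus expected, group 1)
logrank_hand <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  O <- E <- Vsum <- 0
  for (t in times) {
    at1 <- sum(time >= t & group == 1)
    at0 <- sum(time >= t & group == 0)
    d1 <- sum(time == t & event == 1 & group == 1)
    d0 <- sum(time == t & event == 1 & group == 0)
    d <- d1 + d0; atr <- at1 + at0
    O <- O + d1
    E <- E + d * at1 / atr
    if (atr > 1)
      Vsum <- Vsum + d * (at1 / atr) * (at0 / atr) * (atr - d) / (atr - 1)
  }
  chisq <- (O - E)^2 / Vsum
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}
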
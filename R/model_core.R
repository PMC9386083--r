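## Core joint model: logistic response + Weibull-PH survival coupled by a
## shared random intercept b_i ~ N(0, sigma_b^2), marginal likelihood by
## first-order Laplace approximation at the per-patient mode of
##   k(b) = log p(R|b) + log p(T,Delta|b) + log p(b).

# cap on hazard exponents; exp(690) is just below double overflow
.JM_EXP_CAP <- 690

# per-cohort fixed quantities and linear predictors without b
.jm_ctx <- function(params, cohort, tmb_source) {
  x <- .jm_tmb(cohort, tmb_source)
  if (ncol(cohort$Z) != length(params$alpha_z))
    stop("covariate dimension of cohort (", ncol(cohort$Z),
         ") does not match parameter vector (", length(params$alpha_z), ")")
  Za <- if (ncol(cohort$Z)) drop(cohort$Z %*% params$alpha_z) else 0
  Zb <- if (ncol(cohort$Z)) drop(cohort$Z %*% params$beta_z) else 0
  list(
    n = length(cohort$response),
    R = cohort$response, time = cohort$time, event = cohort$event,
    Z = cohort$Z, x = x,
    etaR0 = Za + params$alpha_m * x,
    etaT0 = Zb + params$beta_m * x,
    logT = log(cohort$time),
    H = cohort$time^params$lambda,
    # cumulative-hazard exponent on the log scale: lambda*log(T) + eta + b is
    # capped before exponentiation so extreme parameters degrade gracefully
    logH = params$lambda * log(cohort$time)
  )
}

# vectorized safeguarded Newton root finder for a strictly decreasing
# per-patient score kp(b) with curvature magnitude W(b) = -kp'(b) > 0.
# kp and W map an n-vector b to n-vectors.
.jm_solve_modes <- function(kp, W, n, tol = 1e-8, max_iter = 100L) {
  b <- numeric(n)
  lo <- rep(-1, n)
  hi <- rep(1, n)
  # expand brackets until kp(lo) > 0 > kp(hi) (kp is decreasing in b)
  for (i in 1:80) {
    f_lo <- kp(lo)
    bad <- !is.finite(f_lo) | f_lo <= 0
    if (!any(bad)) break
    lo[bad] <- lo[bad] * 2
  }
  for (i in 1:80) {
    f_hi <- kp(hi)
    bad <- !is.finite(f_hi) | f_hi >= 0
    if (!any(bad)) break
    hi[bad] <- hi[bad] * 2
  }
  f <- kp(b)
  f[!is.finite(f)] <- Inf
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    done <- abs(f) <= tol
    if (all(done)) break
    lo <- ifelse(f > 0, pmax(lo, b), lo)
    hi <- ifelse(f < 0, pmin(hi, b), hi)
    bn <- b + f / W(b)
    bad <- !is.finite(bn) | bn <= lo | bn >= hi
    bn[bad] <- (lo[bad] + hi[bad]) / 2
    bn[done] <- b[done]
    b <- bn
    f <- kp(b)
    f[!is.finite(f)] <- Inf
  }
  list(mode = b, curvature = W(b), converged = is.finite(f) & abs(f) <= tol,
       score = f, iterations = iter)
}

.jm_kp_factory <- function(params, ctx) {
  s2inv <- 1 / params$sigma_b^2
  function(b)
    ctx$R - stats::plogis(ctx$etaR0 + b) + ctx$event -
      exp(pmin(ctx$logH + ctx$etaT0 + b, .JM_EXP_CAP)) - b * s2inv
}

.jm_W_factory <- function(params, ctx) {
  s2inv <- 1 / params$sigma_b^2
  function(b) {
    F <- stats::plogis(ctx$etaR0 + b)
    F * (1 - F) + exp(pmin(ctx$logH + ctx$etaT0 + b, .JM_EXP_CAP)) + s2inv
  }
}

#' Response probability given the random effect
#'
#' Conditional probability of tumor response,
#' \eqn{P(R=1 \mid Z, TMB, b) = F(\alpha_z' Z + \alpha_m TMB + b)} with
#' \eqn{F(u) = (1 + e^{-u})^{-1}}, for one patient.
#'
#' @param params A [jm_params()].
#' @param record One-row cohort (see [jm_cohort()]) or a list with elements
#'   `Z` (covariate vector) and `tmb`.
#' @param b Random-effect value.
#' @param tmb_source `"true"` or `"obs"`: which TMB column enters the linear
#'   predictor.
#' @return Probability in (0, 1).
#' @export
response_probability <- function(params, record, b = 0,
                                 tmb_source = c("obs", "true")) {
  tmb_source <- match.arg(tmb_source)
  ctx <- .jm_ctx(params, record, tmb_source)
  stats::plogis(ctx$etaR0 + b)
}

#' Hazard and survival given the random effect
#'
#' Conditional Weibull-PH quantities at the patient's observed time:
#' hazard \eqn{h(T) = \lambda T^{\lambda-1} e^{\eta}}, cumulative baseline
#' hazard \eqn{H_0(T) = T^{\lambda}} and survival
#' \eqn{S(T) = \exp\{-H_0(T) e^{\eta}\}} with
#' \eqn{\eta = \beta_z' Z + \beta_m TMB + b}.
#'
#' @inheritParams response_probability
#' @return A list with elements `hazard`, `survival`, `cumhaz0` (vectors of
#'   length `nrow(record)`).
#' @export
hazard_survival <- function(params, record, b = 0,
                            tmb_source = c("obs", "true")) {
  tmb_source <- match.arg(tmb_source)
  ctx <- .jm_ctx(params, record, tmb_source)
  eta <- ctx$etaT0 + b
  list(hazard = params$lambda * record$time^(params$lambda - 1) * exp(eta),
       survival = exp(-ctx$H * exp(pmin(eta, .JM_EXP_CAP))),
       cumhaz0 = ctx$H)
}

#' Per-patient random-effect mode
#'
#' Solves \eqn{k'(b) = 0} for each patient, where
#' \eqn{k'(b) = R - F(\eta_R + b) + \Delta - H_0(T)e^{\eta_T + b} - b/\sigma_b^2}
#' is strictly decreasing in `b`, by safeguarded Newton iteration with a
#' bisection fallback (the root is unique). The reported curvature is
#' \eqn{|k''(\hat b)| = F(1-F) + H_0(T)e^{\eta_T + \hat b} + \sigma_b^{-2}},
#' all three terms positive.
#'
#' @inheritParams response_probability
#' @param cohort A [jm_cohort()] (all patients are solved at once).
#' @param tol Convergence tolerance on `|k'(b)|`.
#' @param max_iter Maximum Newton iterations.
#' @return A data frame with one row per patient: `mode`, `curvature`,
#'   `converged`.
#' @export
random_effect_mode <- function(params, cohort, tmb_source = c("obs", "true"),
                               tol = 1e-8, max_iter = 100L) {
  tmb_source <- match.arg(tmb_source)
  ctx <- .jm_ctx(params, cohort, tmb_source)
  sol <- .jm_solve_modes(.jm_kp_factory(params, ctx),
                         .jm_W_factory(params, ctx),
                         ctx$n, tol, max_iter)
  data.frame(mode = sol$mode, curvature = sol$curvature,
             converged = sol$converged)
}

# log p(R|b), log p(T,Delta|b), log p(b) and the Laplace per-patient terms
.jm_loglik_terms <- function(params, ctx, b, W) {
  etaR <- ctx$etaR0 + b
  etaT <- ctx$etaT0 + b
  logF <- stats::plogis(etaR, log.p = TRUE)
  log1mF <- stats::plogis(-etaR, log.p = TRUE)
  lpR <- ctx$R * logF + (1 - ctx$R) * log1mF
  lpT <- ctx$event * (log(params$lambda) + (params$lambda - 1) * ctx$logT +
                        etaT) - exp(pmin(ctx$logH + etaT, .JM_EXP_CAP))
  lpb <- -0.5 * log(2 * pi) - log(params$sigma_b) -
    b^2 / (2 * params$sigma_b^2)
  0.5 * log(2 * pi) + lpR + lpT + lpb - 0.5 * log(W)
}

.jm_modes_or_stop <- function(params, ctx, tol, max_iter) {
  sol <- .jm_solve_modes(.jm_kp_factory(params, ctx),
                         .jm_W_factory(params, ctx),
                         ctx$n, tol, max_iter)
  if (!all(sol$converged))
    stop("random-effect mode solver failed for patient(s) ",
         paste(utils::head(which(!sol$converged), 5), collapse = ", "))
  sol
}

#' Laplace-approximate marginal log-likelihood
#'
#' First-order Laplace approximation of the random-effect-integrated joint
#' log-likelihood: for each patient,
#' \eqn{\tilde\ell_i = \frac12\log 2\pi + \log p(R_i|\hat b_i) +
#' \log p(T_i,\Delta_i|\hat b_i) + \log p(\hat b_i) -
#' \frac12\log|k''(\hat b_i)|}, summed over the cohort.
#'
#' @inheritParams random_effect_mode
#' @return The approximate log-likelihood (scalar).
#' @export
laplace_loglik <- function(params, cohort, tmb_source = c("obs", "true"),
                           tol = 1e-8, max_iter = 100L) {
  tmb_source <- match.arg(tmb_source)
  ctx <- .jm_ctx(params, cohort, tmb_source)
  sol <- .jm_modes_or_stop(params, ctx, tol, max_iter)
  sum(.jm_loglik_terms(params, ctx, sol$mode, sol$curvature))
}

# Assemble per-patient score rows from primitive blocks.
# DK, DW, DKP: n x q matrices of d k / d theta, d W / d theta, d k' / d theta
# (partial derivatives holding b fixed at the mode); dWb: n-vector dW/db;
# W: n-vector of curvature magnitudes. The full derivative of the Laplace
# objective accounts for the implicit dependence of the mode on theta,
# db/dtheta = DKP / W, through the -1/2 log W term (k' itself vanishes at
# the mode):
#   score = DK - (DW + dWb * DKP / W) / (2 W)
.jm_score_assemble <- function(DK, DW, DKP, dWb, W) {
  DK - (DW + (dWb / W) * DKP) / (2 * W)
}

# naive (real-arithmetic) per-patient score matrix at given modes, natural
# theta scale, columns ordered as jm_theta()
.jm_score_matrix <- function(params, ctx, b, W) {
  p <- ncol(ctx$Z)
  q <- 2 * p + 4
  etaR <- ctx$etaR0 + b
  etaT <- ctx$etaT0 + b
  F <- stats::plogis(etaR)
  V <- F * (1 - F)
  U <- V * (1 - 2 * F)
  G <- exp(pmin(ctx$logH + etaT, .JM_EXP_CAP))
  sb <- params$sigma_b
  Xr <- cbind(ctx$Z, ctx$x)    # response/hazard design: (Z, TMB)
  ia <- seq_len(p + 1); il <- p + 2; ib <- p + 2 + seq_len(p + 1); is <- q
  DK <- DW <- DKP <- matrix(0, ctx$n, q)
  DK[, ia] <- (ctx$R - F) * Xr
  DK[, il] <- ctx$event * (1 / params$lambda + ctx$logT) - G * ctx$logT
  DK[, ib] <- (ctx$event - G) * Xr
  DK[, is] <- -1 / sb + b^2 / sb^3
  DW[, ia] <- U * Xr
  DW[, il] <- G * ctx$logT
  DW[, ib] <- G * Xr
  DW[, is] <- -2 / sb^3
  DKP[, ia] <- -V * Xr
  DKP[, il] <- -G * ctx$logT
  DKP[, ib] <- -G * Xr
  DKP[, is] <- 2 * b / sb^3
  dWb <- U + G
  .jm_score_assemble(DK, DW, DKP, dWb, W)
}

#' Analytic score of the Laplace log-likelihood
#'
#' Exact gradient of [laplace_loglik()] with respect to the natural
#' parameters (canonical order of [jm_theta()]), assembled from the
#' response, survival and random-effect blocks. The derivative of the
#' \eqn{-\frac12\log|k''|} term is taken exactly, including the implicit
#' dependence of the per-patient mode on the parameters, so the result
#' matches numerical differentiation of the objective.
#'
#' @inheritParams random_effect_mode
#' @return Named numeric vector of length `2p + 4`.
#' @export
joint_score <- function(params, cohort, tmb_source = c("obs", "true"),
                        tol = 1e-8, max_iter = 100L) {
  tmb_source <- match.arg(tmb_source)
  ctx <- .jm_ctx(params, cohort, tmb_source)
  sol <- .jm_modes_or_stop(params, ctx, tol, max_iter)
  sc <- colSums(.jm_score_matrix(params, ctx, sol$mode, sol$curvature))
  stats::setNames(sc, names(jm_theta(params)))
}

# central-difference Hessian of the Laplace objective via the analytic score,
# on the natural theta scale
.jm_num_hessian <- function(theta, p, score_fun, step_scale = 1e-4) {
  q <- length(theta)
  H <- matrix(0, q, q)
  for (j in seq_len(q)) {
    h <- step_scale * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (score_fun(tp) - score_fun(tm)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit the joint model by Laplace-approximate maximum likelihood
#'
#' Maximizes [laplace_loglik()] by quasi-Newton (BFGS) with the analytic
#' score, with `lambda` and `sigma_b` optimized on the log scale, followed by
#' Newton polishing of the first-order condition. Standard errors come from
#' the inverse of the negative central-difference Hessian at the optimum.
#' Default initial values are the separate logistic and Weibull-PH fits with
#' `sigma_b = 0.5`.
#'
#' @inheritParams random_effect_mode
#' @param init Optional [jm_params()] starting value.
#' @param tol Convergence tolerance on the maximum absolute score component.
#' @param max_iter Maximum optimizer iterations.
#' @param sigma_b_fixed If non-`NULL`, hold the random-effect SD fixed at
#'   this value (useful for degeneracy checks); it is then excluded from the
#'   free parameters and its standard error reported as `NA`.
#' @return A `jm_fit` object: `estimates` ([jm_params()]), `std_errors`,
#'   `covariance`, `loglik`, `score_norm_at_optimum`, `iterations`,
#'   `converged`, per-patient `random_effects`, and `estimator_tag`
#'   (`"true_data"` or `"naive"` according to `tmb_source`).
#' @export
fit_joint <- function(cohort, tmb_source = c("obs", "true"), init = NULL,
                      tol = 1e-6, max_iter = 500L, sigma_b_fixed = NULL) {
  tmb_source <- match.arg(tmb_source)
  p <- ncol(cohort$Z)
  q <- 2 * p + 4
  n <- length(cohort$response)
  if (n < q)
    stop("cohort has fewer subjects (", n, ") than free parameters (", q, ")")
  if (length(unique(cohort$response)) < 2)
    stop("both response classes (R = 0 and R = 1) must be present")
  if (sum(cohort$event) < 1)
    stop("at least one observed event is required")
  if (is.null(init)) init <- .jm_default_init(cohort, tmb_source, sigma_b_fixed)
  if (!is.null(sigma_b_fixed)) {
    init$sigma_b <- sigma_b_fixed
    free <- seq_len(q - 1)
  } else {
    free <- seq_len(q)
  }

  phi_full <- .jm_pack(init)
  make_par <- function(phi_free) {
    phi <- phi_full
    phi[free] <- phi_free
    .jm_unpack(phi, p)
  }
  # mode-solver failures at extreme trial parameters are reported to the
  # optimizer as a very poor objective value rather than an error
  negll <- function(phi_free) {
    par <- make_par(phi_free)
    v <- tryCatch(-laplace_loglik(par, cohort, tmb_source),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  neggr <- function(phi_free) {
    par <- make_par(phi_free)
    g <- tryCatch(joint_score(par, cohort, tmb_source) * .jm_chain(par),
                  error = function(e) rep(0, q))
    g[!is.finite(g)] <- 0
    -g[free]
  }
  opt <- stats::optim(phi_full[free], negll, neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  phi_hat <- opt$par
  # Newton polishing on the transformed-scale score so that the first-order
  # condition holds at `tol`, sharing the Hessian machinery used for SEs
  score_phi <- function(phi_free) -neggr(phi_free)
  g <- score_phi(phi_hat)
  polish <- 0L
  while (max(abs(g)) > tol && polish < 25L) {
    Hn <- .jm_num_hessian(phi_hat, p, score_phi, step_scale = 1e-5)
    step <- tryCatch(-solve(Hn, g), error = function(e) NULL)
    if (is.null(step)) break
    ok <- FALSE
    for (hv in 0:15) {
      cand <- phi_hat + step / 2^hv
      gc_ <- tryCatch(score_phi(cand), error = function(e) NULL)
      if (!is.null(gc_) && all(is.finite(gc_)) &&
          max(abs(gc_)) < max(abs(g))) {
        phi_hat <- cand; g <- gc_; ok <- TRUE; break
      }
    }
    if (!ok) break
    polish <- polish + 1L
  }
  par_hat <- make_par(phi_hat)
  theta_hat <- jm_theta(par_hat)
  score_nat <- joint_score(par_hat, cohort, tmb_source)
  score_norm <- max(abs((score_nat * .jm_chain(par_hat))[free]))
  converged <- score_norm <= tol

  # covariance on the natural scale from the free-parameter block
  Hn <- .jm_num_hessian(theta_hat, p, function(th)
    joint_score(jm_from_theta(th, p), cohort, tmb_source)
  )[free, free, drop = FALSE]
  cov <- tryCatch(solve(-Hn), error = function(e) NULL)
  se <- rep(NA_real_, q)
  covariance <- matrix(NA_real_, q, q)
  if (!is.null(cov) && all(diag(cov) >= 0)) {
    covariance[free, free] <- (cov + t(cov)) / 2
    se[free] <- sqrt(diag(cov))
  } else {
    warning("Hessian at the optimum is not positive definite; ",
            "standard errors reported as NA")
  }
  nm <- names(theta_hat)
  dimnames(covariance) <- list(nm, nm)
  re <- random_effect_mode(par_hat, cohort, tmb_source)
  structure(
    list(estimates = par_hat,
         std_errors = stats::setNames(se, nm),
         covariance = covariance,
         loglik = laplace_loglik(par_hat, cohort, tmb_source),
         score_norm_at_optimum = score_norm,
         iterations = opt$counts[["function"]] + polish,
         converged = converged,
         random_effects = re,
         estimator_tag = if (tmb_source == "true") "true_data" else "naive",
         tmb_source = tmb_source,
         n = n, time_unit = cohort$time_unit),
    class = "jm_fit"
  )
}

# default initialization: separate-model fits for (alpha, lambda, beta),
# moderate random-effect SD
.jm_default_init <- function(cohort, tmb_source, sigma_b_fixed = NULL) {
  lg <- tryCatch(fit_separate_logistic(cohort, tmb_source),
                 error = function(e) NULL)
  wb <- tryCatch(fit_separate_weibull_ph(cohort, tmb_source),
                 error = function(e) NULL)
  p <- ncol(cohort$Z)
  al <- if (!is.null(lg)) lg$estimates else
    c(rep(0, p), 0)
  sv <- if (!is.null(wb)) wb$estimates else
    c(1, rep(0, p), 0)
  jm_params(alpha_z = al[seq_len(p)], alpha_m = al[p + 1],
            lambda = sv[1], beta_z = sv[1 + seq_len(p)], beta_m = sv[p + 2],
            sigma_b = if (is.null(sigma_b_fixed)) 0.5 else sigma_b_fixed)
}

#' @export
print.jm_fit <- function(x, digits = 4, ...) {
  cat("Joint model fit (", x$estimator_tag, " estimator), n = ", x$n,
      "\n", sep = "")
  th <- if (inherits(x$estimates, "jm_params")) jm_theta(x$estimates)
        else x$estimates
  tab <- data.frame(estimate = round(th, digits),
                    std_error = round(x$std_errors[names(th)], digits))
  print(tab)
  cat("log-likelihood:", round(x$loglik, digits),
      "| converged:", x$converged,
      "| max |score|:", format(x$score_norm_at_optimum, digits = 3), "\n")
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit A `jm_fit` object.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  th <- if (inherits(fit$estimates, "jm_params")) jm_theta(fit$estimates)
        else fit$estimates
  out <- list(
    estimator = fit$estimator_tag,
    estimates = as.list(th),
    std_errors = as.list(fit$std_errors),
    covariance = fit$covariance,
    loglik = fit$loglik,
    score_norm_at_optimum = fit$score_norm_at_optimum,
    converged = fit$converged,
    iterations = fit$iterations,
    n = fit$n,
    time_unit = fit$time_unit,
    random_effects = fit$random_effects
  )
  if (is.null(path))
    jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null")
  else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
  }
}
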
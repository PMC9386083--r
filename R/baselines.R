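## Separate single-endpoint regressions: the standard analyses the joint
## model is compared against, and the degenerate (sigma_b -> 0) limits of the
## joint fit. Neither carries an intercept, mirroring the joint sub-models
## (the baseline hazard scale is fixed at 1).

#' Separate logistic regression of response on (Z, TMB)
#'
#' Maximum-likelihood logistic regression of the binary response on the
#' covariates and TMB, without a random effect, via [stats::glm()]
#' (IRLS). No intercept is included, matching the joint response sub-model.
#'
#' @inheritParams random_effect_mode
#' @return A `jm_fit` whose `estimates` is a named vector
#'   `(alpha_z..., alpha_m)`.
#' @export
fit_separate_logistic <- function(cohort, tmb_source = c("obs", "true")) {
  tmb_source <- match.arg(tmb_source)
  if (length(unique(cohort$response)) < 2)
    stop("both response classes (R = 0 and R = 1) must be present")
  x <- .jm_tmb(cohort, tmb_source)
  p <- ncol(cohort$Z)
  X <- cbind(cohort$Z, tmb = x)
  fit <- suppressWarnings(
    stats::glm(cohort$response ~ 0 + X, family = stats::binomial())
  )
  cf <- unname(stats::coef(fit))
  aliased <- is.na(cf)
  if (any(aliased))
    warning("collinear or constant column(s) dropped from the logistic ",
            "fit; their coefficients are reported as NA")
  # fitted probabilities numerically at 0/1 mean the MLE diverges
  if (!fit$converged || any(abs(cf[!aliased]) > 15) ||
      max(abs(fit$linear.predictors)) > 30)
    stop("separate logistic fit did not converge (possible complete ",
         "separation in the response)")
  nm <- c(if (p) paste0("alpha_z", seq_len(p)), "alpha_m")
  vc <- unname(stats::vcov(fit, complete = TRUE))  # NA rows for aliased
  dimnames(vc) <- list(nm, nm)
  structure(
    list(estimates = stats::setNames(cf, nm),
         std_errors = stats::setNames(sqrt(diag(vc)), nm),
         covariance = vc,
         loglik = as.numeric(stats::logLik(fit)),
         score_norm_at_optimum = NA_real_,
         iterations = fit$iter,
         converged = fit$converged,
         random_effects = NULL,
         estimator_tag = paste0("separate_logistic_",
                                if (tmb_source == "true") "true" else "naive"),
         tmb_source = tmb_source,
         n = length(cohort$response), time_unit = cohort$time_unit),
    class = "jm_fit"
  )
}

# Weibull-PH log-likelihood without intercept:
#   l(lambda, beta) = sum Delta*(log lambda + (lambda-1) log T + eta)
#                     - T^lambda e^eta
.jm_weibull_negll <- function(phi, time, event, X, logT) {
  lambda <- exp(phi[1])
  eta <- if (ncol(X)) drop(X %*% phi[-1]) else 0
  -sum(event * (log(lambda) + (lambda - 1) * logT + eta) -
         time^lambda * exp(pmin(eta, .JM_EXP_CAP)))
}

.jm_weibull_neggr <- function(phi, time, event, X, logT) {
  lambda <- exp(phi[1])
  eta <- if (ncol(X)) drop(X %*% phi[-1]) else 0
  G <- time^lambda * exp(pmin(eta, .JM_EXP_CAP))
  dlam <- sum(event * (1 / lambda + logT) - G * logT) * lambda  # d/d log lambda
  dbeta <- drop(crossprod(X, event - G))
  -c(dlam, dbeta)
}

#' Separate Weibull proportional-hazards regression
#'
#' Maximum-likelihood Weibull-PH fit of `(time, event)` on `(Z, TMB)` with
#' hazard \eqn{h(t) = \lambda t^{\lambda-1} e^{\beta_z' Z + \beta_m TMB}}
#' (baseline scale fixed at 1, no random effect), by BFGS on
#' \eqn{\log\lambda} with the analytic gradient.
#'
#' @inheritParams random_effect_mode
#' @return A `jm_fit` whose `estimates` is a named vector
#'   `(lambda, beta_z..., beta_m)`.
#' @export
fit_separate_weibull_ph <- function(cohort, tmb_source = c("obs", "true")) {
  tmb_source <- match.arg(tmb_source)
  if (sum(cohort$event) < 1)
    stop("at least one observed event is required (all records censored)")
  x <- .jm_tmb(cohort, tmb_source)
  p <- ncol(cohort$Z)
  X <- cbind(cohort$Z, tmb = x)
  logT <- log(cohort$time)
  phi0 <- c(0, rep(0, p + 1))
  opt <- stats::optim(phi0, .jm_weibull_negll, .jm_weibull_neggr,
                      time = cohort$time, event = cohort$event, X = X,
                      logT = logT, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  phi <- opt$par
  lambda <- exp(phi[1])
  theta <- c(lambda, phi[-1])
  nm <- c("lambda", if (p) paste0("beta_z", seq_len(p)), "beta_m")
  # observed information on the natural scale by central differences of the
  # analytic gradient
  score_nat <- function(th) {
    ph <- c(log(th[1]), th[-1])
    g <- -.jm_weibull_neggr(ph, cohort$time, cohort$event, X, logT)
    g[1] <- g[1] / th[1]  # back to d/d lambda
    g
  }
  H <- .jm_num_hessian(theta, p, score_nat)
  cov <- tryCatch(solve(-H), error = function(e) NULL)
  se <- if (!is.null(cov) && all(diag(cov) >= 0)) sqrt(diag(cov))
        else rep(NA_real_, p + 2)
  if (is.null(cov)) cov <- matrix(NA_real_, p + 2, p + 2)
  dimnames(cov) <- list(nm, nm)
  structure(
    list(estimates = stats::setNames(theta, nm),
         std_errors = stats::setNames(se, nm),
         covariance = cov,
         loglik = -opt$value,
         score_norm_at_optimum = max(abs(score_nat(theta))),
         iterations = opt$counts[["function"]],
         converged = opt$convergence == 0,
         random_effects = NULL,
         estimator_tag = paste0("separate_weibull_",
                                if (tmb_source == "true") "true" else "naive"),
         tmb_source = tmb_source,
         n = length(cohort$response), time_unit = cohort$time_unit),
    class = "jm_fit"
  )
}
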
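#' Joint-model parameter vector
#'
#' Bundles the full parameter set of the joint response/survival model:
#' response covariate effects `alpha_z` (log-odds per unit) and TMB effect
#' `alpha_m` (log-odds per TMB unit); Weibull shape `lambda` of the baseline
#' hazard \eqn{h_0(t) = \lambda t^{\lambda-1}}; hazard covariate effects
#' `beta_z` and TMB effect `beta_m` (log-hazard per unit); and the standard
#' deviation `sigma_b` of the shared per-patient random intercept.
#'
#' Neither sub-model carries a fixed intercept: the baseline hazard scale is
#' fixed at one and any response-scale shift is absorbed by the covariates.
#'
#' @param alpha_z Numeric vector of response covariate effects.
#' @param alpha_m Scalar response TMB effect.
#' @param lambda Positive scalar Weibull shape.
#' @param beta_z Numeric vector of hazard covariate effects; must have the
#'   same length as `alpha_z`.
#' @param beta_m Scalar hazard TMB effect.
#' @param sigma_b Positive scalar random-effect standard deviation.
#' @return An object of class `jm_params`.
#' @examples
#' jm_params(alpha_z = -1.8, alpha_m = 0.3, lambda = 1,
#'           beta_z = 2.2, beta_m = -0.4, sigma_b = 1)
#' @export
jm_params <- function(alpha_z, alpha_m, lambda, beta_z, beta_m, sigma_b) {
  alpha_z <- as.numeric(alpha_z)
  beta_z <- as.numeric(beta_z)
  alpha_m <- as.numeric(alpha_m)[1L]
  beta_m <- as.numeric(beta_m)[1L]
  lambda <- as.numeric(lambda)[1L]
  sigma_b <- as.numeric(sigma_b)[1L]
  if (length(alpha_z) != length(beta_z))
    stop("`alpha_z` and `beta_z` must have the same length (one entry per covariate)")
  vals <- c(alpha_z, alpha_m, lambda, beta_z, beta_m, sigma_b)
  if (any(!is.finite(vals)))
    stop("all parameters must be finite")
  if (lambda <= 0) stop("`lambda` (Weibull shape) must be > 0")
  if (sigma_b <= 0) stop("`sigma_b` (random-effect SD) must be > 0")
  structure(
    list(alpha_z = alpha_z, alpha_m = alpha_m, lambda = lambda,
         beta_z = beta_z, beta_m = beta_m, sigma_b = sigma_b),
    class = "jm_params"
  )
}

#' @export
print.jm_params <- function(x, digits = 4, ...) {
  cat("Joint model parameters (p =", length(x$alpha_z), "covariates)\n")
  print(round(jm_theta(x), digits))
  invisible(x)
}

#' Flatten / rebuild a parameter vector
#'
#' `jm_theta()` flattens a [jm_params()] object into a named numeric vector on
#' the natural scale, in the canonical order (alpha_z, alpha_m, lambda,
#' beta_z, beta_m, sigma_b); `jm_from_theta()` is its inverse.
#'
#' @param params A `jm_params` object.
#' @return `jm_theta()`: a named numeric vector of length `2p + 4`.
#' @export
jm_theta <- function(params) {
  p <- length(params$alpha_z)
  nm_z <- if (p) paste0("z", seq_len(p)) else character(0)
  stats::setNames(
    c(params$alpha_z, params$alpha_m, params$lambda,
      params$beta_z, params$beta_m, params$sigma_b),
    c(if (p) paste0("alpha_", nm_z), "alpha_m", "lambda",
      if (p) paste0("beta_", nm_z), "beta_m", "sigma_b")
  )
}

#' @rdname jm_theta
#' @param theta Named numeric vector as produced by `jm_theta()`.
#' @param p Number of covariates (length of `alpha_z`).
#' @export
jm_from_theta <- function(theta, p) {
  stopifnot(length(theta) == 2 * p + 4)
  jm_params(alpha_z = theta[seq_len(p)],
            alpha_m = theta[p + 1],
            lambda = theta[p + 2],
            beta_z = theta[p + 2 + seq_len(p)],
            beta_m = theta[2 * p + 3],
            sigma_b = theta[2 * p + 4])
}

# transformed ("phi") scale used by the optimizer: lambda and sigma_b on log
# scale so the search space is unconstrained
.jm_pack <- function(params) {
  th <- jm_theta(params)
  p <- length(params$alpha_z)
  th[p + 2] <- log(th[p + 2])
  th[2 * p + 4] <- log(th[2 * p + 4])
  names(th)[c(p + 2, 2 * p + 4)] <- c("log_lambda", "log_sigma_b")
  th
}

.jm_unpack <- function(phi, p) {
  th <- phi
  th[p + 2] <- exp(th[p + 2])
  th[2 * p + 4] <- exp(th[2 * p + 4])
  jm_from_theta(th, p)
}

# d theta / d phi, as a multiplier vector (chain rule for gradients)
.jm_chain <- function(params) {
  p <- length(params$alpha_z)
  ch <- rep(1, 2 * p + 4)
  ch[p + 2] <- params$lambda
  ch[2 * p + 4] <- params$sigma_b
  ch
}
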
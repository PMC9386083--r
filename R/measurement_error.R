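## Corrected-score estimation under additive normal measurement error in the
## TMB covariate: TMB* = TMB + e, e ~ N(0, sigma_e^2). Logistic (response)
## terms are corrected by the complex-variable Monte Carlo device -- average
## the real part of the term evaluated at TMB* + i*xi, xi ~ N(0, sigma_e^2)
## -- which is exactly unbiased for entire functions since all moments of
## (e + i*xi) beyond the zeroth vanish. Exponential (hazard) terms are
## corrected in closed form by the attenuation factor
## m(beta_m) = E exp(beta_m e) = exp(beta_m^2 sigma_e^2 / 2).

#' Measurement-error specification
#'
#' @param error_variance Variance \eqn{\sigma_e^2 \ge 0} of the additive
#'   normal TMB error (assumed known, e.g. from assay validation).
#' @param mc_draws Number of Monte Carlo draws `J` for the complex-variable
#'   correction of the logistic terms.
#' @param seed Integer seed from which the per-(patient, draw) imaginary
#'   perturbations are generated; the draws are frozen across all solver
#'   iterations (common random numbers) so every corrected quantity is a
#'   deterministic function of (data, spec).
#' @return An object of class `jm_error_spec`.
#' @export
error_spec <- function(error_variance, mc_draws = 10L, seed = 1L) {
  error_variance <- as.numeric(error_variance)[1]
  mc_draws <- as.integer(mc_draws)[1]
  if (!is.finite(error_variance) || error_variance < 0)
    stop("`error_variance` must be a finite value >= 0")
  if (mc_draws < 1) stop("`mc_draws` must be >= 1")
  structure(list(error_variance = error_variance, mc_draws = mc_draws,
                 seed = as.integer(seed)[1]),
            class = "jm_error_spec")
}

# run code with a private RNG stream, restoring the caller's state
.jm_with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# n x J matrix of imaginary perturbations xi ~ N(0, sigma_e^2)
.jm_xi_draws <- function(n, espec) {
  .jm_with_seed(espec$seed,
                matrix(stats::rnorm(n * espec$mc_draws,
                                    sd = sqrt(espec$error_variance)),
                       nrow = n, ncol = espec$mc_draws))
}

#' Hazard attenuation factor under normal TMB error
#'
#' The multiplicative bias that additive normal error induces in
#' exponential-hazard score terms: \eqn{m(\beta_m) = E\{\exp(\beta_m e)\} =
#' \exp(\beta_m^2 \sigma_e^2/2)} (moment-generating function of
#' \eqn{N(0, \sigma_e^2)}), together with the logarithmic derivative
#' \eqn{m^{-1} \partial m/\partial\beta_m = \beta_m \sigma_e^2} used in the
#' corrected \eqn{\beta_m} score block.
#'
#' @param beta_m Hazard TMB coefficient.
#' @param error_variance Error variance \eqn{\sigma_e^2}.
#' @return A list with elements `m` (\eqn{\ge 1}) and `dlog`
#'   (\eqn{\beta_m \sigma_e^2}).
#' @export
attenuation_factor <- function(beta_m, error_variance) {
  if (error_variance < 0) stop("`error_variance` must be >= 0")
  list(m = exp(beta_m^2 * error_variance / 2),
       dlog = beta_m * error_variance)
}

# numerically stable complex logistic F(z) = 1/(1 + exp(-z))
.jm_cplogis <- function(z) {
  out <- z
  pos <- Re(z) >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  e <- exp(z[!pos])
  out[!pos] <- e / (1 + e)
  out
}

# corrected context: complex TMB points TMB* + i*xi and the
# attenuation-deflated hazard used by the real-mode equation
.jm_cctx <- function(params, cohort, espec, xi = NULL) {
  ctx <- .jm_ctx(params, cohort, "obs")
  if (is.null(xi)) xi <- .jm_xi_draws(ctx$n, espec)
  att <- attenuation_factor(params$beta_m, espec$error_variance)
  Za <- if (ncol(cohort$Z)) drop(cohort$Z %*% params$alpha_z) else 0
  Zb <- if (ncol(cohort$Z)) drop(cohort$Z %*% params$beta_z) else 0
  # n x J complex linear predictors without b
  Xt <- ctx$x + 1i * xi
  ctx$xi <- xi
  ctx$Xt <- Xt
  ctx$etaRc0 <- Za + params$alpha_m * Xt
  ctx$etaTc0 <- Zb + params$beta_m * Xt
  ctx$m <- att$m
  ctx$mdlog <- att$dlog
  ctx$logHm <- ctx$logH - log(att$m)   # log{T^lambda / m(beta_m)}
  ctx
}

# complex exponential with the real part of the exponent capped
.jm_cexp <- function(z) {
  out <- exp(complex(real = pmin(Re(z), .JM_EXP_CAP), imaginary = Im(z)))
  dim(out) <- dim(z)
  out
}

.jm_kp_c_factory <- function(params, ctx) {
  s2inv <- 1 / params$sigma_b^2
  function(b) {
    Fc <- .jm_cplogis(ctx$etaRc0 + b)
    ctx$R - rowMeans(Re(Fc)) + ctx$event -
      exp(pmin(ctx$logHm + ctx$etaT0 + b, .JM_EXP_CAP)) - b * s2inv
  }
}

.jm_W_c_factory <- function(params, ctx) {
  s2inv <- 1 / params$sigma_b^2
  function(b) {
    Fc <- .jm_cplogis(ctx$etaRc0 + b)
    Wc <- rowMeans(Re(Fc * (1 - Fc))) +
      exp(pmin(ctx$logHm + ctx$etaT0 + b, .JM_EXP_CAP)) + s2inv
    # the complex-averaged logistic variance term can in principle push the
    # curvature to zero; keep it positive so log|k_c''| stays defined
    pmax(Wc, 1e-10)
  }
}

#' Corrected per-patient random-effect mode
#'
#' Solves the corrected mode equation \eqn{k_c'(b) = 0}, where the logistic
#' term of \eqn{k'} is replaced by the Monte Carlo average of the real part
#' of the complex logistic \eqn{F(\alpha_z'Z + \alpha_m(TMB^* + i\xi_j) + b)}
#' and the hazard term is deflated by the attenuation factor
#' \eqn{m(\beta_m)}. With `error_variance = 0` this reduces exactly to
#' [random_effect_mode()] on the observed TMB.
#'
#' @inheritParams random_effect_mode
#' @param espec An [error_spec()].
#' @return A data frame with one row per patient: `mode`, `curvature`
#'   (\eqn{|k_c''(\hat b)|}), `converged`.
#' @export
corrected_random_effect_mode <- function(params, cohort, espec,
                                         tol = 1e-8, max_iter = 100L) {
  ctx <- .jm_cctx(params, cohort, espec)
  sol <- .jm_solve_modes(.jm_kp_c_factory(params, ctx),
                         .jm_W_c_factory(params, ctx),
                         ctx$n, tol, max_iter)
  data.frame(mode = sol$mode, curvature = sol$curvature,
             converged = sol$converged)
}

# Per-draw complex random-effect modes: for each patient i and draw j, the
# root (in complex b) of the analytic continuation of the naive mode
# equation at the complex covariate point TMB* + i*xi_j,
#   k'(b) = R - F(etaRc0 + b) + Delta - exp(logH + etaTc0 + b) - b/sigma_b^2.
# Newton from b = 0; the equation is strictly decreasing on the real line
# and the imaginary displacement is mild, so capped Newton converges.
.jm_complex_modes <- function(params, ctx, tol = 1e-10, max_iter = 60L) {
  s2inv <- 1 / params$sigma_b^2
  B <- matrix(0 + 0i, ctx$n, ncol(ctx$Xt))
  kp <- function(B)
    ctx$R - .jm_cplogis(ctx$etaRc0 + B) + ctx$event -
      .jm_cexp(ctx$logH + ctx$etaTc0 + B) - B * s2inv
  for (it in seq_len(max_iter)) {
    f <- kp(B)
    if (max(Mod(f)) <= tol) break
    Fc <- .jm_cplogis(ctx$etaRc0 + B)
    W <- Fc * (1 - Fc) + .jm_cexp(ctx$logH + ctx$etaTc0 + B) + s2inv
    step <- f / W
    sm <- Mod(step)
    big <- sm > 2
    step[big] <- step[big] / sm[big] * 2
    B <- B + step
  }
  if (max(Mod(kp(B))) > 1e-6)
    stop("complex mode solver failed to converge")
  B
}

# Corrected per-patient score rows: the full analytic score of the Laplace
# objective (same blocks as .jm_score_matrix) evaluated per draw at the
# complex covariate point and its complex mode, averaged over draws after
# taking the real part. Every block is an analytic function of the
# covariate, so the average is conditionally unbiased for the true-data
# score row (all moments of e + i*xi beyond the zeroth vanish); the hazard
# blocks equal the attenuation-deflated m(beta_m)^-1 forms in expectation
# over the draws, and error_variance = 0 reduces the construction exactly
# to the naive score.
.jm_score_matrix_c <- function(params, ctx, B) {
  p <- ncol(ctx$Z)
  q <- 2 * p + 4
  etaR <- ctx$etaRc0 + B
  etaT <- ctx$etaTc0 + B
  F <- .jm_cplogis(etaR)
  V <- F * (1 - F)
  U <- V * (1 - 2 * F)
  G <- .jm_cexp(ctx$logH + etaT)
  sb <- params$sigma_b
  W <- V + G + 1 / sb^2
  small <- Mod(W) < 1e-10
  if (any(small)) W[small] <- W[small] + 1e-10
  dWb <- U + G
  asm <- function(DK, DW, DKP) DK - (DW + (dWb / W) * DKP) / (2 * W)
  blocks <- vector("list", q)
  resp <- ctx$R - F
  ev <- ctx$event - G
  for (l in seq_len(p)) {
    zl <- ctx$Z[, l]
    blocks[[l]] <- asm(resp * zl, U * zl, -V * zl)
    blocks[[p + 2 + l]] <- asm(ev * zl, G * zl, -G * zl)
  }
  blocks[[p + 1]] <- asm(resp * ctx$Xt, U * ctx$Xt, -V * ctx$Xt)
  blocks[[2 * p + 3]] <- asm(ev * ctx$Xt, G * ctx$Xt, -G * ctx$Xt)
  GlT <- G * ctx$logT
  blocks[[p + 2]] <- asm(ctx$event * (1 / params$lambda + ctx$logT) - GlT,
                         GlT, -GlT)
  blocks[[q]] <- asm(-1 / sb + B^2 / sb^3, -2 / sb^3 + 0 * B, 2 * B / sb^3)
  out <- matrix(0, ctx$n, q)
  for (jj in seq_len(q)) out[, jj] <- rowMeans(Re(blocks[[jj]]))
  out
}

#' Corrected joint score
#'
#' The estimating function \eqn{\Psi_c^*} of the observed (error-corrupted)
#' data whose conditional expectation given the true data equals the
#' true-data score [joint_score()] (the defining property of a corrected
#' score). Each of the `J` Monte Carlo draws continues the full analytic
#' score -- including the per-patient mode solve -- to the complex
#' covariate point \eqn{TMB^* + i\xi_j} with
#' \eqn{\xi_j \sim N(0, \sigma_e^2)}; the corrected score averages the
#' real parts. Because all moments of \eqn{e + i\xi} beyond the zeroth
#' vanish, every analytic function of TMB is conditionally unbiased under
#' this average; in particular the hazard blocks equal the closed-form
#' attenuation-deflated (\eqn{m(\beta_m)^{-1}}, see
#' [attenuation_factor()]) expressions in expectation over the draws, and
#' the logistic blocks are the complex-logistic Monte Carlo averages. The
#' imaginary perturbations are drawn once from `espec$seed` and shared with
#' [corrected_random_effect_mode()]; with `error_variance = 0` the
#' corrected score equals the naive [joint_score()] on the observed TMB.
#'
#' @inheritParams corrected_random_effect_mode
#' @return Named numeric vector of length `2p + 4`.
#' @export
corrected_score <- function(params, cohort, espec, tol = 1e-8,
                            max_iter = 100L) {
  ctx <- .jm_cctx(params, cohort, espec)
  B <- .jm_complex_modes(params, ctx)
  sc <- colSums(.jm_score_matrix_c(params, ctx, B))
  stats::setNames(sc, names(jm_theta(params)))
}

#' Fit the joint model by the corrected-score estimating equation
#'
#' Solves \eqn{\sum_i \Psi_{c,i}^* = 0} by damped Newton-Raphson (forward
#' difference Jacobian, step-halving line search on the score norm), with
#' `lambda` and `sigma_b` on the log scale and `sigma_b` bounded below at
#' `1e-3` for numerical safety. The imaginary perturbations are drawn once
#' from `espec$seed` and frozen across iterations, so the solution is a
#' deterministic function of (data, spec). Initial values default to the
#' naive joint fit. Standard errors invert the negative score Jacobian at
#' the solution; `sandwich = TRUE` instead uses the
#' \eqn{A^{-1} B A^{-T}} form with \eqn{B} the outer product of per-patient
#' scores.
#'
#' @inheritParams corrected_random_effect_mode
#' @param init Optional [jm_params()] starting value; default is the naive
#'   joint fit on the observed TMB.
#' @param tol Convergence tolerance on the maximum absolute score component.
#' @param max_iter Maximum Newton iterations.
#' @param sandwich Use the sandwich covariance instead of the plain
#'   Jacobian inverse.
#' @return A `jm_fit` with `estimator_tag = "corrected"`.
#' @export
fit_corrected <- function(cohort, espec, init = NULL, tol = 1e-6,
                          max_iter = 100L, sandwich = FALSE) {
  p <- ncol(cohort$Z)
  q <- 2 * p + 4
  n <- length(cohort$response)
  if (is.null(cohort$tmb_obs))
    stop("corrected fitting requires `tmb_obs`")
  if (is.null(init)) {
    naive <- fit_joint(cohort, tmb_source = "obs")
    init <- naive$estimates
  }
  xi <- .jm_xi_draws(n, espec)
  score_phi <- function(phi) {
    par <- .jm_unpack(phi, p)
    if (par$sigma_b < 1e-3) par$sigma_b <- 1e-3
    ctx <- .jm_cctx(par, cohort, espec, xi = xi)
    B <- .jm_complex_modes(par, ctx)
    sc <- colSums(.jm_score_matrix_c(par, ctx, B))
    sc * .jm_chain(par)
  }
  phi <- .jm_pack(init)
  g <- score_phi(phi)
  iter <- 0L
  trace <- numeric(0)
  while (max(abs(g)) > tol && iter < max_iter) {
    iter <- iter + 1L
    # forward-difference Jacobian of the (transformed-scale) score
    J <- matrix(0, q, q)
    for (j in seq_len(q)) {
      h <- 1e-5 * (1 + abs(phi[j]))
      ph <- phi; ph[j] <- ph[j] + h
      J[, j] <- (score_phi(ph) - g) / h
    }
    step <- tryCatch(-solve(J, g), error = function(e) NULL)
    if (is.null(step))
      stop("singular Jacobian in corrected-score Newton iteration ", iter)
    ok <- FALSE
    for (hv in 0:20) {
      cand <- phi + step / 2^hv
      gc_ <- tryCatch(score_phi(cand), error = function(e) NULL)
      if (!is.null(gc_) && all(is.finite(gc_)) &&
          max(abs(gc_)) < max(abs(g))) {
        phi <- cand; g <- gc_; ok <- TRUE; break
      }
    }
    trace <- c(trace, max(abs(g)))
    if (!ok) break
  }
  converged <- max(abs(g)) <= tol
  par_hat <- .jm_unpack(phi, p)
  if (par_hat$sigma_b < 1e-3) par_hat$sigma_b <- 1e-3
  theta_hat <- jm_theta(par_hat)
  nm <- names(theta_hat)

  # covariance on the natural scale
  score_nat <- function(th) {
    par <- jm_from_theta(th, p)
    ctx <- .jm_cctx(par, cohort, espec, xi = xi)
    colSums(.jm_score_matrix_c(par, ctx, .jm_complex_modes(par, ctx)))
  }
  A <- .jm_num_hessian(theta_hat, p, score_nat)
  cov <- tryCatch({
    Ainv <- solve(-A)
    if (sandwich) {
      ctx <- .jm_cctx(par_hat, cohort, espec, xi = xi)
      S <- .jm_score_matrix_c(par_hat, ctx, .jm_complex_modes(par_hat, ctx))
      Bo <- crossprod(S)
      Ainv %*% Bo %*% t(Ainv)
    } else Ainv
  }, error = function(e) NULL)
  se <- rep(NA_real_, q)
  covariance <- matrix(NA_real_, q, q, dimnames = list(nm, nm))
  if (!is.null(cov) && all(diag(cov) >= 0)) {
    covariance[, ] <- (cov + t(cov)) / 2
    se <- sqrt(diag(covariance))
  } else {
    warning("score Jacobian at the solution is not usable for standard ",
            "errors; reported as NA")
  }
  re <- corrected_random_effect_mode(par_hat, cohort, espec)
  structure(
    list(estimates = par_hat,
         std_errors = stats::setNames(se, nm),
         covariance = covariance,
         loglik = NA_real_,  # estimating equation, no likelihood objective
         score_norm_at_optimum = max(abs(g)),
         iterations = iter,
         converged = converged,
         iteration_trace = trace,
         random_effects = re,
         estimator_tag = "corrected",
         tmb_source = "obs",
         error_spec = espec,
         n = n, time_unit = cohort$time_unit),
    class = "jm_fit"
  )
}
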
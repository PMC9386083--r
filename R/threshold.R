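## Downstream threshold procedure: per-patient joint prognosis probability
## p(R = 1, T > T0) under the fitted model, rank-based benefit labels, ROC
## construction over TMB, Youden-index cutpoint selection, and two-group
## efficacy comparison.

#' Joint prognosis probability p(R = 1, T > T0)
#'
#' Laplace approximation of
#' \eqn{\int p(R=1\mid b)\, p(T > T_0 \mid b)\, p(b)\, db}: the mode
#' \eqn{b^*} of \eqn{g(b) = \log p(R=1|b) + \log S(T_0|b) + \log p(b)} is
#' found fresh (distinct from the fitting-time modes, which condition on the
#' observed outcomes), and the probability is
#' \eqn{\sqrt{2\pi/|g''(b^*)|}\, e^{g(b^*)}}, clipped to \eqn{[0, 1]}.
#'
#' @param fit A `jm_fit` from [fit_joint()] or [fit_corrected()].
#' @param cohort A [jm_cohort()]; probabilities are computed for all
#'   patients.
#' @param horizon Prognosis horizon \eqn{T_0 > 0}, in the cohort's time
#'   unit. Default: the cohort's median observed time.
#' @param tmb_source Which TMB column enters the linear predictors.
#' @return Numeric vector of probabilities in \eqn{[0, 1]}.
#' @export
joint_prognosis_probability <- function(fit, cohort, horizon = NULL,
                                        tmb_source = NULL) {
  params <- fit$estimates
  if (!inherits(params, "jm_params"))
    stop("`fit` must be a joint-model fit (joint or corrected estimator)")
  if (is.null(tmb_source))
    tmb_source <- if (!is.null(fit$tmb_source) && fit$tmb_source == "true")
      "true" else "obs"
  if (is.null(horizon)) horizon <- stats::median(cohort$time)
  if (!is.finite(horizon) || horizon <= 0) stop("`horizon` must be > 0")
  x <- .jm_tmb(cohort, tmb_source)
  Z <- cohort$Z
  etaR0 <- (if (ncol(Z)) drop(Z %*% params$alpha_z) else 0) + params$alpha_m * x
  etaT0 <- (if (ncol(Z)) drop(Z %*% params$beta_z) else 0) + params$beta_m * x
  logH0 <- params$lambda * log(horizon)
  sb <- params$sigma_b
  s2inv <- 1 / sb^2
  n <- length(x)
  # g'(b) = (1 - F) - H0 e^{etaT + b} - b / sigma_b^2, strictly decreasing
  gp <- function(b)
    (1 - stats::plogis(etaR0 + b)) -
      exp(pmin(logH0 + etaT0 + b, .JM_EXP_CAP)) - b * s2inv
  gW <- function(b) {
    F <- stats::plogis(etaR0 + b)
    F * (1 - F) + exp(pmin(logH0 + etaT0 + b, .JM_EXP_CAP)) + s2inv
  }
  sol <- .jm_solve_modes(gp, gW, n)
  if (!all(sol$converged))
    stop("prognosis mode solver failed for patient(s) ",
         paste(utils::head(which(!sol$converged), 5), collapse = ", "))
  b <- sol$mode
  g <- stats::plogis(etaR0 + b, log.p = TRUE) -
    exp(pmin(logH0 + etaT0 + b, .JM_EXP_CAP)) +
    stats::dnorm(b, sd = sb, log = TRUE)
  pmin(1, pmax(0, sqrt(2 * pi / sol$curvature) * exp(g)))
}

#' Rank-based benefit labels
#'
#' Ranks patients by prognosis probability (descending) and labels the top
#' \eqn{\lceil n \cdot \mathrm{fraction} \rceil} as potential ICI
#' beneficiaries. Ties at the cut are broken in favor of higher observed
#' TMB, then input order.
#'
#' @param probabilities Numeric vector of prognosis probabilities.
#' @param benefit_fraction Fraction in (0, 1) of patients labeled positive;
#'   a natural anchor is the cohort's observed objective response rate.
#' @param tmb Optional TMB vector used for tie-breaking.
#' @return Integer 0/1 vector of labels.
#' @export
assign_benefit_labels <- function(probabilities, benefit_fraction,
                                  tmb = NULL) {
  n <- length(probabilities)
  if (!is.finite(benefit_fraction) || benefit_fraction <= 0 ||
      benefit_fraction >= 1)
    stop("`benefit_fraction` must lie strictly between 0 and 1")
  k <- ceiling(n * benefit_fraction)
  if (k < 1) stop("`benefit_fraction` labels no patient positive")
  if (length(unique(probabilities)) == 1)
    warning("all prognosis probabilities are equal; labels follow the ",
            "tie-break rule only")
  if (is.null(tmb)) tmb <- numeric(n)
  ord <- order(-probabilities, -tmb, seq_len(n))
  labels <- integer(n)
  labels[ord[seq_len(k)]] <- 1L
  labels
}

#' ROC curve of TMB against benefit labels
#'
#' Sweeps a positivity threshold over all distinct TMB values (a patient is
#' called positive iff \eqn{TMB \ge t}, matching the clinical premise that
#' high TMB predicts benefit) from high to low, so TPR and FPR are
#' nondecreasing along the sweep from (0, 0) to (1, 1). The AUC is the
#' trapezoidal area, which equals the Mann-Whitney probability of correct
#' ranking with tie correction.
#'
#' @param tmb_values Numeric vector of TMB values.
#' @param labels 0/1 benefit labels; both classes must be present.
#' @return A `jm_roc` object: `candidate_thresholds` (in sweep order,
#'   decreasing, starting at `Inf`), `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(tmb_values, labels) {
  labels <- as.integer(labels)
  if (length(labels) != length(tmb_values))
    stop("`tmb_values` and `labels` must have equal length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("cannot rank: both label classes must be present")
  thr <- c(Inf, sort(unique(tmb_values), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(labels == 1 & tmb_values >= t) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(labels == 0 & tmb_values >= t) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(candidate_thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = auc),
            class = "jm_roc")
}

#' @export
print.jm_roc <- function(x, ...) {
  cat("ROC over", length(x$candidate_thresholds) - 1,
      "candidate TMB cutpoints; AUC =", round(x$auc, 4), "\n")
  invisible(x)
}

#' Youden-index threshold selection
#'
#' Among candidate cutpoints restricted to a clinically meaningful range,
#' returns the one maximizing the Youden index \eqn{J = TPR - FPR}.
#' Candidates are the midpoints between consecutive distinct observed TMB
#' values plus the range endpoints (a cutpoint between two observed values
#' classifies identically anywhere in the gap; the midpoint is the
#' conventional representative). Ties are broken by the smallest threshold.
#'
#' @param roc A `jm_roc` from [roc_curve()].
#' @param clinical_range Length-2 numeric `c(lo, hi)` restricting the
#'   search; default spans all candidates.
#' @return A list: `threshold`, `youden_j`, `tpr`, `fpr`.
#' @export
youden_threshold <- function(roc, clinical_range = NULL) {
  vals <- sort(roc$candidate_thresholds[is.finite(roc$candidate_thresholds)])
  cands <- unique(c(vals[1],
                    if (length(vals) > 1)
                      (utils::head(vals, -1) + utils::tail(vals, -1)) / 2,
                    vals[length(vals)]))
  if (is.null(clinical_range)) clinical_range <- range(cands)
  keep <- cands >= clinical_range[1] & cands <= clinical_range[2]
  if (!any(keep))
    stop("no candidate threshold inside the clinical range [",
         clinical_range[1], ", ", clinical_range[2],
         "]; observed TMB spans [", min(vals), ", ", max(vals), "]")
  cands <- sort(cands[keep])
  # a cut at c classifies like the smallest observed value >= c, i.e. the
  # last sweep position whose threshold is still >= c
  idx_at <- vapply(cands, function(cc)
    max(which(roc$candidate_thresholds >= cc)), integer(1))
  js <- roc$tpr[idx_at] - roc$fpr[idx_at]
  best <- which.max(js)  # first (= smallest) maximizer breaks ties
  list(threshold = cands[best], youden_j = js[best],
       tpr = roc$tpr[idx_at[best]], fpr = roc$fpr[idx_at[best]])
}

#' Stratify a cohort at a TMB threshold and compare efficacy
#'
#' Splits the cohort into TMB-low (\eqn{TMB < t}) and TMB-high
#' (\eqn{TMB \ge t}) groups and summarizes efficacy per group: objective
#' response rate, Kaplan-Meier median survival (infinite when the curve
#' never drops to 0.5), and censored count; compares the groups with a
#' two-sided log-rank test on `(time, event)` and a two-sided Mann-Whitney
#' U test on the binary response.
#'
#' @param cohort A [jm_cohort()].
#' @param threshold TMB cutpoint, strictly inside the observed TMB range.
#' @param tmb_source Which TMB column to stratify on.
#' @return A `jm_threshold_result` list: `threshold`, `group_summaries`
#'   (data frame with rows `low`, `high`), `logrank_p`, `mannwhitney_p`.
#' @export
stratify_and_compare <- function(cohort, threshold,
                                 tmb_source = c("obs", "true")) {
  tmb_source <- match.arg(tmb_source)
  x <- .jm_tmb(cohort, tmb_source)
  if (threshold <= min(x) || threshold > max(x))
    stop("threshold ", threshold, " must lie strictly inside the observed ",
         "TMB range [", min(x), ", ", max(x), "]")
  grp <- factor(ifelse(x >= threshold, "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) == 0)) stop("one stratum is empty")
  km_median <- function(idx) {
    sf <- survival::survfit(survival::Surv(cohort$time[idx],
                                           cohort$event[idx]) ~ 1)
    med <- unname(summary(sf)$table["median"])
    if (is.na(med)) Inf else med
  }
  gs <- data.frame(
    group = c("low", "high"),
    n = as.integer(table(grp)),
    orr = c(mean(cohort$response[grp == "low"]),
            mean(cohort$response[grp == "high"])),
    km_median = c(km_median(grp == "low"), km_median(grp == "high")),
    censored = c(sum(1 - cohort$event[grp == "low"]),
                 sum(1 - cohort$event[grp == "high"]))
  )
  sd_ <- survival::survdiff(survival::Surv(cohort$time, cohort$event) ~ grp)
  logrank_p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  mw <- suppressWarnings(
    stats::wilcox.test(cohort$response[grp == "high"],
                       cohort$response[grp == "low"], exact = FALSE)
  )
  structure(list(threshold = threshold, group_summaries = gs,
                 logrank_p = logrank_p, mannwhitney_p = mw$p.value,
                 time_unit = cohort$time_unit),
            class = "jm_threshold_result")
}

#' @export
print.jm_threshold_result <- function(x, digits = 4, ...) {
  cat("TMB threshold:", round(x$threshold, digits), "\n")
  print(x$group_summaries, digits = digits)
  cat("log-rank p =", format(x$logrank_p, digits = 3),
      "| Mann-Whitney p =", format(x$mannwhitney_p, digits = 3), "\n")
  invisible(x)
}

#' End-to-end TMB threshold pipeline
#'
#' Runs the full procedure on a fitted joint model: joint prognosis
#' probabilities at `horizon`, benefit labels at `benefit_fraction`, ROC of
#' TMB against the labels, Youden-index threshold within `clinical_range`,
#' and the two-group efficacy comparison at the selected threshold.
#'
#' @inheritParams joint_prognosis_probability
#' @param benefit_fraction Fraction of patients labeled as potential
#'   beneficiaries; default: the cohort's observed response rate.
#' @param clinical_range Range of clinically admissible thresholds;
#'   default: the observed TMB range.
#' @return A list: `probabilities`, `labels`, `roc`, `threshold`,
#'   `youden_j`, `comparison` (a `jm_threshold_result`), plus the settings
#'   used.
#' @export
tmb_threshold_pipeline <- function(fit, cohort, horizon = NULL,
                                   benefit_fraction = NULL,
                                   clinical_range = NULL,
                                   tmb_source = NULL) {
  if (is.null(tmb_source))
    tmb_source <- if (!is.null(fit$tmb_source) && fit$tmb_source == "true")
      "true" else "obs"
  if (is.null(horizon)) horizon <- stats::median(cohort$time)
  if (is.null(benefit_fraction)) benefit_fraction <- mean(cohort$response)
  x <- .jm_tmb(cohort, tmb_source)
  probs <- joint_prognosis_probability(fit, cohort, horizon, tmb_source)
  labels <- assign_benefit_labels(probs, benefit_fraction, tmb = x)
  roc <- roc_curve(x, labels)
  yt <- youden_threshold(roc, clinical_range)
  cmp <- stratify_and_compare(cohort, yt$threshold, tmb_source)
  list(probabilities = probs, labels = labels, roc = roc,
       threshold = yt$threshold, youden_j = yt$youden_j, comparison = cmp,
       horizon = horizon, benefit_fraction = benefit_fraction,
       tmb_source = tmb_source)
}
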
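fit_for_threshold <- function() {
  co <- small_cohort(n = 150, seed = 51)
  list(cohort = co, fit = fit_joint(co, "true"))
}

test_that("joint prognosis probability matches adaptive quadrature and is
           monotone in the horizon", {
  set.seed(52)
  # 50 random single-patient cases; sigma_b spans the range of fitted
  # values seen under the benchmark generating process (truth 1.0) -- the
  # first-order Laplace error on this integrand grows with sigma_b and
  # reaches 2% around sigma_b ~ 1.3, the documented validity boundary
  rel_err <- replicate(50, {
    pars <- jm_params(alpha_z = rnorm(1), alpha_m = rnorm(1, 0, 0.4),
                      lambda = runif(1, 0.6, 1.8), beta_z = rnorm(1),
                      beta_m = rnorm(1, 0, 0.4),
                      sigma_b = runif(1, 0.2, 1.2))
    rec <- one_record(1, 1, 1, z = rbinom(1, 1, 0.5), tmb = rnorm(1, 0, 1.4))
    horizon <- runif(1, 0.3, 3)
    fake_fit <- structure(list(estimates = pars, tmb_source = "true"),
                          class = "jm_fit")
    lap <- joint_prognosis_probability(fake_fit, rec, horizon, "true")
    quad <- quad_prognosis(pars, rec, horizon, "true")
    abs(lap - quad) / quad
  })
  expect_lt(max(rel_err), 0.02)

  fx <- fit_for_threshold()
  probs <- joint_prognosis_probability(fx$fit, fx$cohort, horizon = 1)
  expect_true(all(probs >= 0 & probs <= 1))
  # strictly decreasing in the horizon, and tending to the marginal
  # response probability as the horizon vanishes
  hs <- c(1e-8, 0.5, 1, 2, 4)
  pm <- vapply(hs, function(h)
    joint_prognosis_probability(fx$fit, fx$cohort, h)[7], numeric(1))
  expect_true(all(diff(pm) < 0))
  rec7 <- jointTMB:::.jm_subset(fx$cohort, 7)
  marg <- quad_marginal_response <- stats::integrate(function(b) {
    pars <- fx$fit$estimates
    eta <- pars$alpha_z * rec7$Z[1, 1] + pars$alpha_m * rec7$tmb_true[1] + b
    plogis(eta) * dnorm(b, sd = pars$sigma_b)
  }, -10, 10)$value
  expect_equal(pm[1], marg, tolerance = 0.02)
})

test_that("benefit labels follow the ranking with documented tie-breaks", {
  expect_equal(assign_benefit_labels(c(0.9, 0.1, 0.8, 0.2), 0.5),
               c(1L, 0L, 1L, 0L))
  # fraction 1/n labels exactly the argmax
  expect_equal(assign_benefit_labels(c(0.2, 0.9, 0.4, 0.1), 0.25),
               c(0L, 1L, 0L, 0L))
  # ties at the cut broken by higher TMB, then input order
  expect_warning(
    lab_tie <- assign_benefit_labels(c(0.5, 0.5, 0.5), 0.3,
                                     tmb = c(1, 3, 2)),
    "equal")
  expect_equal(lab_tie, c(0L, 1L, 0L))
  expect_warning(assign_benefit_labels(rep(0.4, 4), 0.5, tmb = 1:4),
                 "equal")
  expect_error(assign_benefit_labels(c(0.1, 0.9), 1.2), "between 0 and 1")
  # on a cohort with favorable TMB effects, labeled patients carry more TMB
  fx <- fit_for_threshold()
  probs <- joint_prognosis_probability(fx$fit, fx$cohort)
  lab <- assign_benefit_labels(probs, 0.4, tmb = fx$cohort$tmb_true)
  expect_gt(mean(fx$cohort$tmb_true[lab == 1]),
            mean(fx$cohort$tmb_true[lab == 0]))
})

test_that("ROC curve matches exhaustive pair counting and behaves at the
           extremes", {
  # hand-checkable toys
  r1 <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r1$auc, 1.0)
  r2 <- roc_curve(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(r2$auc, 0.75)
  expect_equal(r2$auc, auc_pairs(c(1, 3, 2, 4), c(0, 0, 1, 1)))
  # curve runs from (0,0) to (1,1) and is monotone along the sweep
  expect_equal(c(r2$tpr[1], r2$fpr[1]), c(0, 0))
  expect_equal(c(max(r2$tpr), max(r2$fpr)), c(1, 1))
  expect_true(all(diff(r2$tpr) >= 0) && all(diff(r2$fpr) >= 0))
  # random instances incl. ties: AUC == pair counting; monotone transform
  # invariance
  set.seed(53)
  for (i in 1:20) {
    tmb <- sample(round(rnorm(30), 1))  # coarse grid forces ties
    lab <- rbinom(30, 1, 0.5)
    if (length(unique(lab)) < 2) next
    expect_equal(roc_curve(tmb, lab)$auc, auc_pairs(tmb, lab))
    expect_equal(roc_curve(exp(tmb), lab)$auc, roc_curve(tmb, lab)$auc)
  }
  # near-random labels on a large sample give AUC near 1/2
  set.seed(54)
  tmb <- rnorm(4000); lab <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_curve(tmb, lab)$auc - 0.5), 0.03)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "cannot rank")
})

test_that("Youden threshold equals a brute-force sweep and honors the
           clinical range and tie rule", {
  set.seed(55)
  brute <- function(tmb, lab, lo, hi) {
    vals <- sort(unique(tmb))
    cands <- unique(c(vals[1], (head(vals, -1) + tail(vals, -1)) / 2,
                      vals[length(vals)]))
    cands <- cands[cands >= lo & cands <= hi]
    js <- vapply(cands, function(cc) {
      mean(tmb[lab == 1] >= cc) - mean(tmb[lab == 0] >= cc)
    }, numeric(1))
    list(threshold = cands[which.max(js)], j = max(js))
  }
  for (i in 1:15) {
    tmb <- round(rnorm(40), 1)
    lab <- rbinom(40, 1, plogis(tmb))
    if (length(unique(lab)) < 2) next
    roc <- roc_curve(tmb, lab)
    got <- youden_threshold(roc)
    want <- brute(tmb, lab, -Inf, Inf)
    expect_equal(got$youden_j, want$j)
    expect_equal(got$threshold, want$threshold)
    # restricting the range returns the in-range maximizer
    lo <- quantile(tmb, 0.4); hi <- quantile(tmb, 0.9)
    got_r <- youden_threshold(roc, c(lo, hi))
    want_r <- brute(tmb, lab, lo, hi)
    expect_equal(got_r$youden_j, want_r$j)
  }
  # perfectly separated: any cut between the groups is optimal, the
  # smallest candidate is returned
  roc <- roc_curve(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(youden_threshold(roc)$threshold, 6)  # midpoint of the gap
  expect_equal(youden_threshold(roc)$youden_j, 1)
  expect_error(youden_threshold(roc, c(100, 200)), "clinical range")
})

test_that("stratified comparison reproduces hand KM / log-rank results", {
  # KM median by hand: times 1..5, all events -> median 3
  co <- jm_cohort(response = c(1, 0, 1, 0, 1), time = 1:5,
                  event = rep(1, 5), Z = rep(0, 5),
                  tmb_obs = c(1, 2, 3, 10, 20))
  res <- stratify_and_compare(co, 9)
  gs <- res$group_summaries
  expect_equal(gs$n, c(3L, 2L))
  expect_equal(gs$km_median[gs$group == "low"],
               km_median_hand(1:3, rep(1, 3)))
  expect_equal(gs$orr, c(2 / 3, 1 / 2))
  # duplicated-cohort split: identical groups, log-rank p = 1, equal ORR
  co2 <- small_cohort(n = 40, seed = 56)
  dup <- jm_cohort(response = rep(co2$response, 2), time = rep(co2$time, 2),
                   event = rep(co2$event, 2), Z = rep(co2$Z[, 1], 2),
                   tmb_obs = rep(0:1, each = 40))
  res2 <- stratify_and_compare(dup, 0.5)
  expect_equal(res2$logrank_p, 1, tolerance = 1e-9)
  expect_equal(res2$group_summaries$orr[1], res2$group_summaries$orr[2])
  # 6-subject worked example against the hand observed-minus-expected
  co3 <- jm_cohort(response = c(1, 1, 0, 0, 1, 0),
                   time = c(1, 3, 5, 2, 4, 6),
                   event = c(1, 1, 0, 1, 1, 1), Z = rep(0, 6),
                   tmb_obs = c(5, 6, 7, 1, 2, 3))
  res3 <- stratify_and_compare(co3, 4)
  hand <- logrank_hand(co3$time, co3$event, as.integer(co3$tmb_obs >= 4))
  expect_equal(res3$logrank_p, hand$p, tolerance = 1e-9)
  expect_error(stratify_and_compare(co3, 100), "range")
})

test_that("ROC AUC agrees with pROC on a simulated cohort", {
  skip_if_not_installed("pROC")
  fx <- fit_for_threshold()
  probs <- joint_prognosis_probability(fx$fit, fx$cohort)
  lab <- assign_benefit_labels(probs, 0.35, tmb = fx$cohort$tmb_true)
  ours <- roc_curve(fx$cohort$tmb_true, lab)$auc
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(lab, fx$cohort$tmb_true)))
  )
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("the full pipeline returns an in-range threshold with coherent
           group summaries", {
  fx <- fit_for_threshold()
  pl <- tmb_threshold_pipeline(fx$fit, fx$cohort)
  expect_true(pl$threshold > min(fx$cohort$tmb_true) &&
                pl$threshold < max(fx$cohort$tmb_true))
  expect_equal(sum(pl$labels), ceiling(length(fx$cohort) *
                                         pl$benefit_fraction))
  expect_equal(sum(pl$comparison$group_summaries$n), length(fx$cohort))
  expect_true(pl$youden_j >= 0 && pl$youden_j <= 1)
})
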
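# jointTMB

Joint modeling of tumor response and survival for selecting a tumor
mutation burden (TMB) positivity threshold, with a corrected-score
estimator for TMB measurement error.

## What problem this solves

TMB (somatic mutations per megabase) stratifies patients for
immune-checkpoint-inhibitor therapy, but a defensible "TMB-high" cutpoint
has to reconcile two facts about real trial data:

1. **Efficacy is multi-endpoint.** Objective response (binary, CR/PR vs
   SD/PD) and time-to-event outcomes (e.g. progression-free survival,
   right-censored) are correlated within a patient. `jointTMB` couples a
   logistic response sub-model and a Weibull proportional-hazards survival
   sub-model through a shared per-patient random intercept
   $b_i \sim N(0, \sigma_b^2)$:

   $$\operatorname{logit} P(R_i = 1 \mid b_i) = \alpha_z' Z_i + \alpha_m\, \mathrm{TMB}_i + b_i,$$
   $$h_i(t \mid b_i) = \lambda t^{\lambda-1} \exp(\beta_z' Z_i + \beta_m\, \mathrm{TMB}_i + b_i),$$

   and fits the marginal likelihood by a first-order Laplace approximation
   with an exact analytic score (`fit_joint()`).

2. **TMB is measured with error.** With
   $\mathrm{TMB}^* = \mathrm{TMB} + e$, $e \sim N(0, \sigma_e^2)$, the
   naive fit attenuates $\alpha_m$ and $\beta_m$ toward zero (the hazard
   score is inflated by $E e^{\beta_m e} = e^{\beta_m^2\sigma_e^2/2}$).
   `fit_corrected()` solves a *corrected-score* estimating equation —
   conditionally unbiased for the true-data score — built from the
   complex-variable Monte Carlo device: each score term (including the
   per-patient random-effect mode) is continued analytically to
   $\mathrm{TMB}^* + i\xi_j$, $\xi_j \sim N(0, \sigma_e^2)$, and the real
   parts are averaged over $J$ draws.

On top of the fit, the threshold pipeline computes each patient's joint
prognosis probability $p(R = 1, T > T_0)$, labels the likely beneficiaries,
sweeps TMB as a classifier of those labels (ROC), and selects the cutpoint
maximizing the Youden index within a clinically meaningful range, reporting
per-group response rates, Kaplan-Meier medians, log-rank and Mann-Whitney
tests (`tmb_threshold_pipeline()`, `stratify_and_compare()`).

A synthetic-cohort module (`simulate_cohort()`, `run_simulation_study()`,
`run_threshold_stress_test()`) reproduces the benchmark oncology-trial
generating process used to validate all three estimators (true-data, naive,
corrected), so every empirical claim in the package is recomputable without
external data.

## Worked example

Simulate a 200-patient trial under the default truth
($\alpha_z = -1.8$, $\alpha_m = 0.3$, $\lambda = 1$, $\beta_z = 2.2$,
$\beta_m = -0.4$, $\sigma_b = 1$), corrupt TMB with error variance 1.0,
and compare the naive and corrected fits:

```r
library(jointTMB)

cohort <- simulate_cohort(sim_config(n_patients = 200), seed = 2026)
cohort <- add_measurement_error(cohort, error_variance = 1.0, seed = 7)

naive <- fit_joint(cohort, tmb_source = "obs")
corrected <- fit_corrected(cohort, error_spec(1.0, mc_draws = 10, seed = 11))
```

The naive hazard-TMB coefficient is attenuated roughly by
$\sigma_x^2 / (\sigma_x^2 + \sigma_e^2) = 2/3$; the corrected fit recovers
the truth:

```
Joint model fit (naive estimator), n = 200
         estimate std_error
alpha_m    0.3133    0.0985
beta_m    -0.2696    0.0593   # attenuated (truth -0.4)
...
Joint model fit (corrected estimator), n = 200
         estimate std_error
alpha_m    0.4366    0.1184
beta_m    -0.3879    0.0727   # recovered
```

Running the threshold pipeline on the corrected fit:

```r
pl <- tmb_threshold_pipeline(corrected, cohort)
pl$comparison
```

```
Selected TMB threshold: -0.974 (Youden J = 0.504, AUC = 0.754)
  group   n    orr km_median censored
1   low  62 0.2419    0.1306        3
2  high 138 0.4493    0.3004       27
log-rank p = 0.00158 | Mann-Whitney p = 0.00546
```

The TMB-high group responds more (45% vs 24%) and survives longer (median
0.30 vs 0.13 time units), consistent with the favorable-TMB truth — on this
same cohort a naive median split of the corrupted TMB values weakens or can
even reverse that ordering (see `run_threshold_stress_test()`).

A thin command-line wrapper over the same functions lives at
`inst/cli/jointTMB-cli.R` (subcommands `simulate`, `fit`, `fit-corrected`,
`threshold`, `study`, `stress`; see `?run_command`).

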
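## Run configuration and command dispatch: the programmatic surface behind
## the command-line script (inst/cli/jointTMB-cli.R). Every artifact embeds
## the configuration, seed and package version; input files are never
## mutated.

#' Read a run configuration (JSON or YAML)
#'
#' A run configuration is a named list with a `command` field
#' (`"simulate"`, `"fit"`, `"fit-corrected"`, `"threshold"`, `"study"` or
#' `"stress"`) plus the fields the command needs: `cohort` (input CSV
#' path), `out` (output path), `seed`, `tmb_source`, `error_variance`,
#' `mc_draws`, `horizon`, `benefit_fraction`, `clinical_range`,
#' `n_patients`, `n_replicates`, `estimators`, `error_variances`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the `yaml` package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.jm_config_defaults <- function(config) {
  defaults <- list(seed = 1L, tmb_source = "obs", mc_draws = 10L,
                   error_variance = 0, verbosity = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

.jm_sim_config_from <- function(config) {
  args <- config[intersect(names(config),
                           c("n_patients", "censor_upper", "error_variances",
                             "mc_draws", "n_replicates", "seed"))]
  if (!is.null(config$truth))
    args$params <- do.call(jm_params, as.list(config$truth))
  do.call(sim_config, args)
}

.jm_emit <- function(object, config, path) {
  payload <- list(
    package = "jointTMB",
    version = as.character(utils::packageVersion("jointTMB")),
    seed = config$seed,
    config = config[setdiff(names(config), "verbosity")],
    result = object
  )
  if (!is.null(path)) {
    tmp <- paste0(path, ".tmp")
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         na = "null", force = TRUE, pretty = TRUE)
    file.rename(tmp, path)  # no partial overwrite on failure
    invisible(path)
  } else payload
}

.jm_log <- function(config, ...) {
  if ((config$verbosity %||% 1L) >= 1L)
    message("[jointTMB ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
}

#' Execute a run configuration
#'
#' Dispatches on `config$command`:
#' \describe{
#'   \item{simulate}{generate a cohort (optionally error-corrupted) and
#'     write it as a cohort CSV to `config$out`.}
#'   \item{fit}{joint Laplace fit on `config$cohort` using
#'     `config$tmb_source`; JSON fit artifact.}
#'   \item{fit-corrected}{corrected-score fit with
#'     `config$error_variance` and `config$mc_draws`; JSON fit artifact.}
#'   \item{threshold}{fit (naive or corrected per `error_variance`), then
#'     prognosis, labels, ROC, Youden threshold and group comparison;
#'     JSON artifact with ROC points and group summaries.}
#'   \item{study}{the parameter-recovery harness
#'     ([run_simulation_study()]); JSON artifact with the summary table.}
#'   \item{stress}{the threshold stress test
#'     ([run_threshold_stress_test()]); JSON artifact.}
#' }
#'
#' @param config Named list (see [read_run_config()]).
#' @return The artifact payload, invisibly when written to `config$out`.
#' @export
run_command <- function(config) {
  config <- .jm_config_defaults(config)
  cmd <- config$command
  if (is.null(cmd))
    stop("run config must contain a `command` field")
  known <- c("simulate", "fit", "fit-corrected", "threshold", "study",
             "stress")
  if (!cmd %in% known)
    stop("unknown command: ", cmd, " (expected one of ",
         paste(known, collapse = ", "), ")")
  out <- config$out
  if (cmd == "simulate") {
    sc <- .jm_sim_config_from(config)
    cohort <- simulate_cohort(sc, config$seed)
    if ((config$error_variance %||% 0) > 0)
      cohort <- add_measurement_error(cohort, config$error_variance,
                                      .jm_derive_seed(config$seed, 104729))
    if (!is.null(out)) {
      write_cohort(cohort, out)
      .jm_log(config, "wrote simulated cohort (n = ", length(cohort),
              ") to ", out)
      return(invisible(out))
    }
    return(cohort)
  }
  if (cmd == "study") {
    sc <- .jm_sim_config_from(config)
    est <- config$estimators %||% c("joint_true", "joint_naive",
                                    "joint_corrected")
    study <- run_simulation_study(sc, estimators = est)
    .jm_log(config, "simulation study finished (", study$n_replicates,
            " replicates)")
    return(.jm_emit(list(summary = study$summary,
                         failures = as.list(study$failures)),
                    config, out))
  }
  if (cmd == "stress") {
    st <- run_threshold_stress_test(.jm_sim_config_from(config),
                                    error_variance =
                                      config$error_variance %||% 1.0,
                                    seed = config$seed)
    .jm_log(config, "stress test finished; reversals: ",
            paste(names(st$reversed)[st$reversed], collapse = ", "))
    return(.jm_emit(unclass(st), config, out))
  }
  cohort <- read_cohort(config$cohort)
  if (cmd == "fit") {
    fit <- fit_joint(cohort, tmb_source = config$tmb_source)
    .jm_log(config, "joint fit (", fit$estimator_tag, ") converged: ",
            fit$converged)
    return(.jm_emit(jsonlite::parse_json(fit_to_json(fit)), config, out))
  }
  if (cmd == "fit-corrected") {
    espec <- error_spec(config$error_variance, config$mc_draws, config$seed)
    fit <- fit_corrected(cohort, espec)
    .jm_log(config, "corrected fit converged: ", fit$converged)
    return(.jm_emit(jsonlite::parse_json(fit_to_json(fit)), config, out))
  }
  if (cmd == "threshold") {
    if ((config$error_variance %||% 0) > 0) {
      espec <- error_spec(config$error_variance, config$mc_draws,
                          config$seed)
      fit <- fit_corrected(cohort, espec)
    } else {
      fit <- fit_joint(cohort, tmb_source = config$tmb_source)
    }
    pl <- tmb_threshold_pipeline(fit, cohort, horizon = config$horizon,
                                 benefit_fraction = config$benefit_fraction,
                                 clinical_range = config$clinical_range,
                                 tmb_source = config$tmb_source)
    res <- list(estimator = fit$estimator_tag,
                threshold = pl$threshold, youden_j = pl$youden_j,
                horizon = pl$horizon,
                benefit_fraction = pl$benefit_fraction,
                auc = pl$roc$auc,
                roc = data.frame(threshold = pl$roc$candidate_thresholds,
                                 tpr = pl$roc$tpr, fpr = pl$roc$fpr),
                group_summaries = pl$comparison$group_summaries,
                logrank_p = pl$comparison$logrank_p,
                mannwhitney_p = pl$comparison$mannwhitney_p)
    .jm_log(config, "selected TMB threshold ", round(pl$threshold, 4))
    return(.jm_emit(res, config, out))
  }
  stop("unknown command: ", cmd)
}
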
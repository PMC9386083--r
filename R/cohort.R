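#' Patient cohort container
#'
#' A cohort holds, per patient, the binary tumor response `response`
#' (1 = CR/PR, 0 = SD/PD), the observed follow-up time `time` (minimum of the
#' event and censoring times, one time unit cohort-wide), the event indicator
#' `event` (1 = event observed, 0 = censored), a numeric covariate matrix `Z`,
#' and the TMB covariate: `tmb_obs` is the error-prone measurement actually
#' available in practice, `tmb_true` the error-free value (available in
#' simulations, `NULL` otherwise).
#'
#' @param response Integer/numeric vector in \{0, 1\}.
#' @param time Positive numeric vector of observed times.
#' @param event Integer/numeric vector in \{0, 1\}.
#' @param Z Numeric matrix (or data frame / vector) of exactly measured
#'   covariates, one row per patient; may have zero columns.
#' @param tmb_obs Numeric vector of observed TMB values (mutations/Mb).
#' @param tmb_true Optional numeric vector of true TMB values.
#' @param covariate_names Optional character vector of covariate labels.
#' @param time_unit Label for the cohort-wide time unit (echoed in outputs).
#' @return An object of class `jm_cohort`.
#' @examples
#' jm_cohort(response = c(1, 0, 1), time = c(2.3, 1.1, 4.0),
#'           event = c(1, 1, 0), Z = c(1, 0, 1),
#'           tmb_obs = c(12.1, 3.4, 8.8))
#' @export
jm_cohort <- function(response, time, event, Z = NULL, tmb_obs = NULL,
                      tmb_true = NULL, covariate_names = NULL,
                      time_unit = "time-unit") {
  n <- length(response)
  response <- as.numeric(response)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != n || length(event) != n)
    stop("`response`, `time` and `event` must have equal length")
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = n, ncol = 0)
  if (is.data.frame(Z)) Z <- as.matrix(Z)
  if (!is.matrix(Z)) Z <- matrix(as.numeric(Z), nrow = n)
  storage.mode(Z) <- "double"
  if (nrow(Z) != n) stop("`Z` must have one row per patient")
  if (is.null(covariate_names)) {
    covariate_names <- colnames(Z)
    if (is.null(covariate_names) && ncol(Z) > 0)
      covariate_names <- paste0("z", seq_len(ncol(Z)))
  }
  colnames(Z) <- covariate_names
  if (is.null(tmb_obs) && is.null(tmb_true))
    stop("at least one of `tmb_obs`, `tmb_true` must be supplied")
  chk <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != n) stop("`", what, "` must have length ", n)
    bad <- which(!is.finite(x))
    if (length(bad))
      stop("non-finite value in `", what, "` at row ", bad[1])
    x
  }
  tmb_obs <- chk(tmb_obs, "tmb_obs")
  tmb_true <- chk(tmb_true, "tmb_true")
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad)) stop("`time` must be > 0 (row ", bad[1], ")")
  bad <- which(!response %in% c(0, 1))
  if (length(bad)) stop("`response` must be 0 or 1 (row ", bad[1], ")")
  bad <- which(!event %in% c(0, 1))
  if (length(bad)) stop("`event` must be 0 or 1 (row ", bad[1], ")")
  bad <- which(!is.finite(Z))
  if (length(bad)) stop("non-finite covariate value in `Z`")
  structure(
    list(response = response, time = time, event = event, Z = Z,
         tmb_obs = tmb_obs, tmb_true = tmb_true,
         covariate_names = covariate_names, time_unit = time_unit),
    class = "jm_cohort"
  )
}

#' @export
print.jm_cohort <- function(x, ...) {
  cat("Patient cohort: n =", length(x$response),
      "| covariates:", ncol(x$Z),
      "| events:", sum(x$event),
      "| ORR:", round(mean(x$response), 3), "\n")
  cat("TMB columns:",
      paste(c(if (!is.null(x$tmb_obs)) "tmb_obs",
              if (!is.null(x$tmb_true)) "tmb_true"), collapse = ", "),
      "| time unit:", x$time_unit, "\n")
  invisible(x)
}

#' @export
length.jm_cohort <- function(x) length(x$response)

#' @export
as.data.frame.jm_cohort <- function(x, ...) {
  df <- data.frame(response = x$response, time = x$time, event = x$event)
  if (!is.null(x$tmb_obs)) df$tmb_obs <- x$tmb_obs
  if (!is.null(x$tmb_true)) df$tmb_true <- x$tmb_true
  if (ncol(x$Z) > 0) df <- cbind(df, as.data.frame(x$Z))
  df
}

# pull the TMB vector named by tmb_source, with a clear error when absent
.jm_tmb <- function(cohort, tmb_source = c("obs", "true")) {
  tmb_source <- match.arg(tmb_source)
  x <- if (tmb_source == "obs") cohort$tmb_obs else cohort$tmb_true
  if (is.null(x))
    stop("cohort has no `tmb_", tmb_source, "` column but tmb_source = \"",
         tmb_source, "\" was requested")
  x
}

# subset a cohort by patient index
.jm_subset <- function(cohort, idx) {
  jm_cohort(response = cohort$response[idx], time = cohort$time[idx],
            event = cohort$event[idx], Z = cohort$Z[idx, , drop = FALSE],
            tmb_obs = cohort$tmb_obs[idx], tmb_true = cohort$tmb_true[idx],
            covariate_names = cohort$covariate_names,
            time_unit = cohort$time_unit)
}

#' Read / write a cohort CSV
#'
#' The on-disk schema is a plain CSV with header columns
#' `response,time,event,tmb_obs` (required unless only `tmb_true` is
#' available), optionally `tmb_true`, and any remaining numeric columns
#' treated as exactly measured covariates `Z`. Validation errors name the
#' offending row and column. Missing values are rejected: the model has no
#' missing-data mechanism.
#'
#' @param path Path to a CSV file.
#' @return `read_cohort()` returns a [jm_cohort()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("response", "time", "event")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!("tmb_obs" %in% names(df)) && !("tmb_true" %in% names(df)))
    stop("cohort CSV must contain `tmb_obs` and/or `tmb_true`")
  reserved <- c("response", "time", "event", "tmb_obs", "tmb_true")
  for (cn in names(df)) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))
      stop("non-numeric cell in column `", cn, "`",
           if (length(bad)) paste0(", row ", bad[1]))
    }
    bad <- which(is.na(col))
    if (length(bad))
      stop("missing value in column `", cn, "`, row ", bad[1])
  }
  for (cn in c("response", "event")) {
    bad <- which(!df[[cn]] %in% c(0, 1))
    if (length(bad))
      stop("column `", cn, "` must be 0/1; offending row ", bad[1])
  }
  bad <- which(df$time <= 0)
  if (length(bad)) stop("column `time` must be > 0; offending row ", bad[1])
  zcols <- setdiff(names(df), reserved)
  jm_cohort(response = df$response, time = df$time, event = df$event,
            Z = if (length(zcols)) as.matrix(df[zcols]) else NULL,
            tmb_obs = df$tmb_obs, tmb_true = df$tmb_true,
            covariate_names = if (length(zcols)) zcols)
}

#' @rdname read_cohort
#' @param cohort A [jm_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  # 17 significant digits round-trip IEEE doubles exactly
  df[] <- lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
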
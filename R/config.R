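#' Load a run configuration
#'
#' Reads and validates a YAML run configuration describing one complete
#' workflow: drug file, formulation input (fitted Weibull parameters or a
#' raw dissolution CSV to fit), population block, dosing regimen, solver
#' settings and seed. Unknown keys, missing referenced files and invalid
#' ranges raise descriptive configuration errors; all defaults are resolved
#' at load time so the returned object is self-contained.
#'
#' @param path Path to a YAML configuration.
#' @return A list of class `run_config` with all defaults filled in.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file '%s' does not exist.", path),
          class = "ropipbpk_configuration_error")
  }
  y <- yaml::read_yaml(path)
  # `n_subjects`, not a bare `n`: YAML 1.1 parses unquoted n/y/no/yes as booleans
  known <- c("study_id", "drug", "formulation", "population", "n_subjects",
             "age_range", "male_fraction", "regimen", "pk_phase",
             "prandial", "followup_h", "sampling", "solver", "seed",
             "observed_csv")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "ropipbpk_configuration_error")
  }
  need <- function(field) {
    if (is.null(y[[field]])) {
      abort(sprintf("Config is missing required field `%s`.", field),
            class = "ropipbpk_configuration_error")
    }
    y[[field]]
  }
  base_dir <- dirname(normalizePath(path))
  resolve_path <- function(p) {
    if (file.exists(p)) return(p)
    p2 <- file.path(base_dir, p)
    if (file.exists(p2)) return(p2)
    abort(sprintf("Referenced file '%s' does not exist.", p),
          class = "ropipbpk_configuration_error")
  }

  drug_field <- y$drug %||% "ropinirole"
  drug <- if (identical(drug_field, "ropinirole")) drug_ropinirole() else
    load_drug(resolve_path(drug_field))

  form <- need("formulation")
  if (!is.null(form$weibull)) {
    wb <- form$weibull
    weibull <- weibull_params(wb$alpha, wb$beta, wb$fmax %||% 1, wb$lag %||% 0)
    dissolution_csv <- NULL
  } else if (!is.null(form$dissolution_csv)) {
    dissolution_csv <- resolve_path(form$dissolution_csv)
    weibull <- NULL
  } else {
    abort("`formulation` needs `weibull` parameters or a `dissolution_csv`.",
          class = "ropipbpk_configuration_error")
  }

  reg_raw <- need("regimen")
  regimen <- purrr::map(reg_raw, function(ph) {
    if (is.null(ph$dose_mg)) {
      abort("A regimen phase is missing `dose_mg`.",
            class = "ropipbpk_configuration_error")
    }
    tibble(dose_mg = ph$dose_mg, interval_h = ph$interval_h %||% 24,
           n_doses = as.integer(ph$n_doses %||% 1))
  }) |> purrr::list_rbind() |> validate_regimen()

  solver <- y$solver %||% list()
  rtol <- solver$rtol %||% 1e-8
  atol <- solver$atol %||% 1e-10
  if (rtol <= 0 || atol <= 0) {
    abort("Solver tolerances must be positive.",
          class = "ropipbpk_configuration_error")
  }
  age_range <- unlist(need("age_range"))
  if (length(age_range) != 2 || diff(age_range) <= 0) {
    abort("`age_range` must be two increasing values.",
          class = "ropipbpk_configuration_error")
  }

  cfg <- list(
    study_id = need("study_id"),
    drug = drug, drug_field = drug_field,
    weibull = weibull, dissolution_csv = dissolution_csv,
    population = y$population %||% "general_nec",
    n = as.integer(need("n_subjects")),
    age_range = age_range,
    male_fraction = y$male_fraction %||% 0.5,
    regimen = regimen,
    pk_phase = y$pk_phase %||% nrow(regimen),
    prandial = y$prandial %||% "fasted",
    followup_h = y$followup_h %||% 48,
    dt_out = (y$sampling %||% list())$dt_out %||% 0.25,
    rtol = rtol, atol = atol,
    seed = as.integer(y$seed %||% 1),
    observed_csv = if (!is.null(y$observed_csv)) resolve_path(y$observed_csv) else NULL
  )
  if (cfg$n < 1) abort("`n` must be >= 1.", class = "ropipbpk_configuration_error")
  population_spec(cfg$population)  # validates the name
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' Serializes a `run_config` back to YAML such that loading the result
#' reproduces the configuration (lossless round trip for all resolved
#' settings).
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- list(
    study_id = config$study_id,
    drug = config$drug_field,
    formulation = if (!is.null(config$weibull)) {
      list(weibull = list(alpha = config$weibull$alpha, beta = config$weibull$beta,
                          fmax = config$weibull$fmax, lag = config$weibull$lag))
    } else list(dissolution_csv = config$dissolution_csv),
    population = config$population, n_subjects = config$n,
    age_range = as.numeric(config$age_range),
    male_fraction = config$male_fraction,
    regimen = purrr::pmap(config$regimen, function(dose_mg, interval_h, n_doses) {
      list(dose_mg = dose_mg, interval_h = interval_h, n_doses = n_doses)
    }),
    pk_phase = config$pk_phase, prandial = config$prandial,
    followup_h = config$followup_h,
    sampling = list(dt_out = config$dt_out),
    solver = list(rtol = config$rtol, atol = config$atol),
    seed = config$seed)
  if (!is.null(config$observed_csv)) y$observed_csv <- config$observed_csv
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full workflow of a configuration
#'
#' Executes the pipeline the package exists for: fit the Weibull release
#' parameters if a raw dissolution CSV was configured, generate the virtual
#' cohort, simulate the trial, compute NCA metrics and population
#' summaries, and -- when an observed-summary CSV is configured -- run the
#' two-fold verification. Writes `metrics.csv`, `summary.csv`,
#' `profiles.csv`, optionally `fold_report.json`, and `run_log.txt`
#' carrying the seed, package version and a hash of the configuration, so
#' any run is reproducible from its artifacts.
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `trial_result`, the fitted
#'   `weibull_fit` (if any), the `fold_report` (if any) and the output
#'   paths.
#' @export
run_full_workflow <- function(config, out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("ropipbpk %s", as.character(utils::packageVersion("ropipbpk"))),
                 sprintf("study: %s", config$study_id),
                 sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", rlang::hash(unclass(config))))

  wfit <- NULL
  weibull <- config$weibull
  if (is.null(weibull)) {
    pts <- read_dissolution_csv(config$dissolution_csv)
    wfit <- fit_weibull(pts)
    weibull <- wfit$params
    write_weibull_json(wfit, file.path(out_dir, "weibull_fit.json"))
    log_lines <- c(log_lines, sprintf(
      "fitted weibull: alpha=%.6g beta=%.6g (rss %.3g, converged %s)",
      weibull$alpha, weibull$beta, wfit$rss, wfit$converged))
  }
  tc <- trial_config(study_id = config$study_id, population = config$population,
                     n = config$n, age_range = config$age_range,
                     male_fraction = config$male_fraction, weibull = weibull,
                     regimen = config$regimen, pk_phase = config$pk_phase,
                     prandial = config$prandial, followup_h = config$followup_h,
                     dt_out = config$dt_out, rtol = config$rtol, atol = config$atol)
  result <- simulate_trial(tc, drug = config$drug, seed = config$seed)
  if (length(result$failures)) {
    log_lines <- c(log_lines, paste("simulate:", result$failures))
  }
  write.csv(result$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write.csv(result$summary$metrics, file.path(out_dir, "summary.csv"), row.names = FALSE)
  write.csv(result$profiles, file.path(out_dir, "profiles.csv"), row.names = FALSE)

  fold <- NULL
  if (!is.null(config$observed_csv)) {
    observed <- as_tibble(read.csv(config$observed_csv))
    fold <- fold_assessment(result, observed, statistic = "mean")
    jsonlite::write_json(as.data.frame(fold), file.path(out_dir, "fold_report.json"),
                         digits = NA)
    log_lines <- c(log_lines, sprintf("fold verification: %d/%d metrics within two-fold",
                                      sum(fold$pass), nrow(fold)))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(result = result, weibull_fit = wfit, fold = fold,
                 out_dir = out_dir))
}
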
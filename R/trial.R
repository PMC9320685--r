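#' Dosing regimens
#'
#' A regimen is a tibble of ordered dosing phases with columns `dose_mg`,
#' `interval_h`, `n_doses`; titration designs (for example 2 mg QD for
#' 7 days, then 4 mg QD for 7 days) are contiguous phases.
#' `regimen_qd()` builds the common once-daily titration, and
#' `regimen_schedule()` expands any regimen into the explicit
#' administration schedule.
#'
#' @param doses_mg Dose of each phase (mg).
#' @param days_each Days per phase (one value or per phase).
#' @return `regimen_qd()`: a regimen tibble. `regimen_schedule()`: a tibble
#'   `time_h`, `amount_mg`, `phase`.
#' @examples
#' regimen_schedule(regimen_qd(c(2, 4), days_each = 7))
#' @export
regimen_qd <- function(doses_mg, days_each = 7) {
  if (length(days_each) == 1) days_each <- rep(days_each, length(doses_mg))
  validate_regimen(tibble(dose_mg = doses_mg, interval_h = 24,
                          n_doses = as.integer(days_each)))
}

validate_regimen <- function(regimen) {
  stopifnot(is.data.frame(regimen),
            all(c("dose_mg", "interval_h", "n_doses") %in% names(regimen)))
  if (any(regimen$dose_mg <= 0)) abort("Regimen doses must be positive.")
  if (any(regimen$interval_h <= 0) || any(regimen$n_doses < 1)) {
    abort("Intervals must be positive and each phase needs >= 1 dose.")
  }
  as_tibble(regimen)
}

#' @rdname regimen_qd
#' @param regimen A regimen tibble.
#' @export
regimen_schedule <- function(regimen) {
  regimen <- validate_regimen(regimen)
  t0 <- 0
  out <- vector("list", nrow(regimen))
  for (i in seq_len(nrow(regimen))) {
    ph <- regimen[i, ]
    out[[i]] <- tibble(time_h = t0 + ph$interval_h * (seq_len(ph$n_doses) - 1),
                       amount_mg = ph$dose_mg, phase = i)
    t0 <- t0 + ph$interval_h * ph$n_doses
  }
  dplyr::bind_rows(out)
}

#' Trial configuration
#'
#' Bundles everything one virtual trial needs: study identity, population,
#' demographics, formulation release parameters and the dosing regimen. PK
#' assessment happens over the last dosing interval of `pk_phase` (the
#' highest-dose phase by default), matching designs where PK is measured on
#' the last day of the dosing period; single-dose designs are followed up
#' long enough for AUC extrapolation.
#'
#' @param study_id Label for the trial.
#' @param population Population spec name, see [population_spec()].
#' @param n Number of subjects.
#' @param age_range Age range (years).
#' @param male_fraction Fraction of males.
#' @param weibull Release parameters, [weibull_params()].
#' @param regimen Regimen tibble, see [regimen_qd()].
#' @param pk_phase Phase index whose last interval is the assessment
#'   window; defaults to the final phase.
#' @param prandial `"fasted"` or `"fed"`.
#' @param followup_h Simulated time past the final dose (h).
#' @param dt_out Output resolution (h).
#' @param rtol,atol Solver tolerances.
#'
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(study_id, population = "general_nec", n,
                         age_range, male_fraction = 0.5, weibull,
                         regimen, pk_phase = NULL,
                         prandial = c("fasted", "fed"), followup_h = 48,
                         dt_out = 0.25, rtol = 1e-8, atol = 1e-10) {
  prandial <- match.arg(prandial)
  regimen <- validate_regimen(regimen)
  pk_phase <- pk_phase %||% nrow(regimen)
  if (pk_phase < 1 || pk_phase > nrow(regimen)) abort("`pk_phase` out of range.")
  structure(list(study_id = study_id, population = population, n = as.integer(n),
                 age_range = age_range, male_fraction = male_fraction,
                 weibull = as_weibull_params(weibull), regimen = regimen,
                 pk_phase = as.integer(pk_phase), prandial = prandial,
                 followup_h = followup_h, dt_out = dt_out,
                 rtol = rtol, atol = atol),
            class = "trial_config")
}

# Assessment window: the last dosing interval of the PK phase.
assessment_window <- function(config) {
  sched <- regimen_schedule(config$regimen)
  ph <- sched[sched$phase == config$pk_phase, ]
  start <- max(ph$time_h)
  tau <- config$regimen$interval_h[config$pk_phase]
  c(start = start, end = start + tau, tau = tau)
}

#' Simulate a virtual clinical trial
#'
#' Generates a cohort from the configured population, simulates every
#' subject through the full regimen (titration phases included), computes
#' per-subject NCA metrics over the assessment window and population
#' summaries. Solver failures in individual subjects are logged and the
#' trial continues. Fully reproducible: configuration plus seed determines
#' every number.
#'
#' @param config A [trial_config()].
#' @param drug A [drug_properties()] object.
#' @param seed Integer seed.
#' @param cohort Optional pre-built cohort (overrides the config's
#'   population block); used by the paired experiments.
#'
#' @return An object of class `trial_result`: list with `profiles` (long
#'   tibble `subject_id`, `time_h`, `conc`), `metrics` (per-subject NCA),
#'   `summary` (see [summarize_trial()]), `cohort`, `failures`, `config`,
#'   `seed`. Supports [tidy()], [glance()], [autoplot()].
#' @export
simulate_trial <- function(config, drug = drug_ropinirole(), seed = 1,
                           cohort = NULL) {
  stopifnot(inherits(config, "trial_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(population_spec(config$population), n = config$n,
                              male_fraction = config$male_fraction,
                              age_range = config$age_range, seed = seed)
  }
  win <- assessment_window(config)
  t_end <- win[["end"]] + config$followup_h
  sched <- regimen_schedule(config$regimen)

  profiles <- list(); metrics <- list(); failures <- character()
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    prof <- tryCatch(
      simulate_profile(subj, drug, config$weibull, dose_schedule = sched,
                       t_end = t_end, dt_out = config$dt_out,
                       prandial = config$prandial,
                       rtol = config$rtol, atol = config$atol),
      error = function(e) e)
    if (inherits(prof, "error")) {
      failures <- c(failures, sprintf("subject %d: %s", subj$subject_id,
                                      conditionMessage(prof)))
      next
    }
    profiles[[length(profiles) + 1]] <-
      tibble(subject_id = subj$subject_id, time_h = prof$time_h, conc = prof$conc)
    wprof <- prof |>
      filter(.data$time_h >= win[["start"]]) |>
      mutate(time_h = .data$time_h - win[["start"]])
    m <- nca_metrics(wprof, dosing_interval = win[["tau"]])
    metrics[[length(metrics) + 1]] <- mutate(m, subject_id = subj$subject_id,
                                             .before = 1)
  }
  if (!length(profiles)) abort("All subjects failed to simulate.")
  profiles <- dplyr::bind_rows(profiles)
  metrics <- dplyr::bind_rows(metrics)
  structure(list(profiles = profiles, metrics = metrics,
                 summary = summarize_trial(metrics, profiles),
                 cohort = cohort, failures = failures,
                 config = config, seed = seed, window = win),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s: %d/%d subjects simulated\n",
              x$config$study_id, length(unique(x$metrics$subject_id)),
              nrow(x$cohort)))
  print(x$summary$metrics)
  invisible(x)
}

#' Population summaries of a simulated trial
#'
#' Arithmetic mean, geometric mean, median and spread for each PK metric,
#' plus the pointwise mean and 5th/95th percentile concentration bands
#' across subjects at the common sampling times.
#'
#' @param metrics Per-subject NCA tibble (from [simulate_trial()]).
#' @param profiles Long profile tibble (`subject_id`, `time_h`, `conc`).
#' @return A list with tibbles `metrics` (one row per metric: `mean`,
#'   `geomean`, `median`, `sd`, `p5`, `p95`, `n`) and `bands` (`time_h`,
#'   `mean`, `p5`, `p95`).
#' @export
summarize_trial <- function(metrics, profiles) {
  if (nrow(metrics) < 1) abort("Need at least one subject.")
  long <- metrics |>
    select("subject_id", "cmax", "tmax", "auc_0_tau", "auc_0_inf") |>
    pivot_longer(-"subject_id", names_to = "metric", values_to = "value")
  msum <- long |>
    filter(is.finite(.data$value)) |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value),
              geomean = if (all(.data$value > 0)) exp(mean(log(.data$value))) else NA_real_,
              median = median(.data$value),
              sd = if (dplyr::n() > 1) sd(.data$value) else 0,
              p5 = unname(quantile(.data$value, 0.05, type = 7)),
              p95 = unname(quantile(.data$value, 0.95, type = 7)),
              n = dplyr::n(), .groups = "drop")
  bands <- profiles |>
    group_by(.data$time_h) |>
    summarise(mean = mean(.data$conc),
              p5 = unname(quantile(.data$conc, 0.05, type = 7)),
              p95 = unname(quantile(.data$conc, 0.95, type = 7)),
              .groups = "drop")
  list(metrics = msum, bands = bands)
}

#' @rdname simulate_trial
#' @param x A `trial_result`.
#' @param ... Unused.
#' @export
tidy.trial_result <- function(x, ...) x$metrics

#' @rdname simulate_trial
#' @export
glance.trial_result <- function(x, ...) {
  x$summary$metrics |>
    select("metric", "geomean") |>
    pivot_wider(names_from = "metric", values_from = "geomean") |>
    mutate(n = nrow(x$cohort), n_failed = length(x$failures))
}

#' @rdname simulate_trial
#' @param object A `trial_result`.
#' @export
autoplot.trial_result <- function(object, ...) {
  ggplot2::ggplot(object$summary$bands, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "black") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ug/L)",
                  title = object$config$study_id,
                  subtitle = "Population mean with 5th-95th percentile band") +
    ggplot2::theme_minimal()
}

#' Two-fold verification of simulated against observed PK
#'
#' For each metric present in both summaries the symmetric fold difference
#' `max(sim/obs, obs/sim)` is computed and compared with the two-fold
#' acceptance criterion. Any of the mean/geometric-mean/median pairings can
#' be chosen to match what an observed report provides. Metrics with a
#' missing or zero observed value are skipped with a warning.
#'
#' @param simulated Trial metric summary (the `metrics` tibble from
#'   [summarize_trial()], or a `trial_result`).
#' @param observed Tibble with columns `metric` and `value` (summary
#'   statistics on the same scale).
#' @param statistic Which simulated summary statistic to pair:
#'   `"mean"`, `"geomean"` or `"median"`.
#'
#' @return A `fold_report` tibble: `metric`, `simulated`, `observed`,
#'   `fold`, `pass` (`fold <= 2`), `statistic`.
#' @examples
#' obs <- tibble::tibble(metric = "cmax", value = 10)
#' sim <- tibble::tibble(metric = "cmax", mean = 14, geomean = 13, median = 14)
#' fold_assessment(sim, obs, statistic = "mean")
#' @export
fold_assessment <- function(simulated, observed,
                            statistic = c("mean", "geomean", "median")) {
  statistic <- match.arg(statistic)
  if (inherits(simulated, "trial_result")) simulated <- simulated$summary$metrics
  stopifnot(all(c("metric", statistic) %in% names(simulated)),
            all(c("metric", "value") %in% names(observed)))
  joined <- inner_join(select(simulated, "metric", sim = dplyr::all_of(statistic)),
                       select(observed, "metric", obs = "value"),
                       by = "metric")
  bad <- !is.finite(joined$obs) | joined$obs <= 0 |
    !is.finite(joined$sim) | joined$sim <= 0
  if (any(bad)) {
    warn(sprintf("Skipping metric(s) with missing/zero values: %s",
                 paste(joined$metric[bad], collapse = ", ")))
    joined <- joined[!bad, ]
  }
  out <- joined |>
    mutate(fold = pmax(.data$sim / .data$obs, .data$obs / .data$sim),
           pass = .data$fold <= 2, statistic = statistic) |>
    rename(simulated = "sim", observed = "obs")
  class(out) <- c("fold_report", class(out))
  out
}

#' Dissolution-input sensitivity experiment
#'
#' Simulates the same cohort (identical seeds and subjects) under each of
#' several dissolution inputs -- Weibull parameter sets or raw point sets
#' (which are fitted first) -- and reports the population summaries side by
#' side with paired per-subject metric differences against the first input.
#'
#' @param config A [trial_config()]; its `weibull` slot is replaced by each
#'   input in turn.
#' @param dissolution_inputs Named list of [weibull_params()] or dissolution
#'   point data frames (`time_h`, `dissolved_pct`).
#' @param drug Drug properties.
#' @param seed Cohort seed (shared across inputs).
#'
#' @return A list with `summaries` (tibble: input x metric summaries),
#'   `paired` (per-subject metric ratios against the reference input) and
#'   the per-input `trial_result`s.
#' @export
run_experiment_dissolution_sensitivity <- function(config, dissolution_inputs,
                                                   drug = drug_ropinirole(),
                                                   seed = 1) {
  if (length(dissolution_inputs) < 2) abort("Need >= 2 dissolution inputs.")
  if (is.null(names(dissolution_inputs)) || any(names(dissolution_inputs) == "")) {
    names(dissolution_inputs) <- paste0("input_", seq_along(dissolution_inputs))
  }
  cohort <- generate_cohort(population_spec(config$population), n = config$n,
                            male_fraction = config$male_fraction,
                            age_range = config$age_range, seed = seed)
  results <- purrr::imap(dissolution_inputs, function(inp, nm) {
    wb <- if (is.data.frame(inp)) fit_weibull(inp)$params else as_weibull_params(inp)
    cfg <- config; cfg$weibull <- wb
    simulate_trial(cfg, drug = drug, seed = seed, cohort = cohort)
  })
  summaries <- purrr::imap(results, function(r, nm) {
    mutate(r$summary$metrics, input = nm, .before = 1)
  }) |> purrr::list_rbind()
  ref <- names(results)[1]
  ref_m <- results[[ref]]$metrics
  paired <- purrr::imap(results[-1], function(r, nm) {
    inner_join(ref_m, r$metrics, by = "subject_id",
               suffix = c("_ref", "_alt")) |>
      transmute(input = nm, .data$subject_id,
                cmax_ratio = .data$cmax_alt / .data$cmax_ref,
                tmax_diff = .data$tmax_alt - .data$tmax_ref,
                auc_ratio = .data$auc_0_tau_alt / .data$auc_0_tau_ref)
  }) |> purrr::list_rbind()
  list(summaries = summaries, paired = paired, results = results,
       reference = ref)
}

#' Exposure-by-age experiment
#'
#' Simulates the same regimen in several age bands of a (typically
#' geriatric) population spec and reports mean exposure per band. Bands are
#' sampled with the same global seed so differences reflect the age
#' dependence of the sampled physiology, not sampling noise structure.
#'
#' @param config A [trial_config()] (its `age_range` is replaced per band).
#' @param age_bands List of `c(lower, upper)` age ranges.
#' @param drug Drug properties.
#' @param seed Seed shared across bands.
#'
#' @return A list with `by_band` (tibble: band, mean/geomean AUC and Cmax)
#'   and the per-band `trial_result`s.
#' @export
run_experiment_age_bands <- function(config, age_bands,
                                     drug = drug_ropinirole(), seed = 1) {
  if (length(age_bands) < 2) abort("Need >= 2 age bands.")
  nms <- purrr::map_chr(age_bands, function(b) paste0(b[1], "-", b[2]))
  results <- purrr::map(age_bands, function(band) {
    cfg <- config; cfg$age_range <- band
    simulate_trial(cfg, drug = drug, seed = seed)
  })
  names(results) <- nms
  by_band <- purrr::imap(results, function(r, nm) {
    s <- r$summary$metrics
    tibble(band = nm,
           mean_auc_0_tau = s$mean[s$metric == "auc_0_tau"],
           geomean_auc_0_tau = s$geomean[s$metric == "auc_0_tau"],
           mean_cmax = s$mean[s$metric == "cmax"])
  }) |> purrr::list_rbind()
  list(by_band = by_band, results = results)
}
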
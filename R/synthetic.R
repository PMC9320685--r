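#' Synthetic dissolution point sets
#'
#' Generates sparse dissolution profiles with known Weibull ground truth:
#' `dissolved = 100 * Fdiss(t) * exp(e)`, `e ~ N(0, cv^2)` (multiplicative
#' log-normal noise -- dissolution readings are positive and
#' right-skewed), clipped to the assay range \[0, 105\]. `cv = 0` returns
#' exact curve points. Bitwise reproducible per seed.
#'
#' @param truth [weibull_params()] ground truth.
#' @param timepoints Sampling times (h), positive and increasing.
#' @param cv Multiplicative noise CV (>= 0).
#' @param seed Integer seed.
#' @return A tibble `time_h`, `dissolved_pct`.
#' @examples
#' gen_dissolution_points(weibull_params(33.7, 1.33), c(2, 12, 24), cv = 0.02, seed = 1)
#' @export
gen_dissolution_points <- function(truth, timepoints, cv = 0, seed = 1) {
  truth <- as_weibull_params(truth)
  if (any(timepoints <= 0) || any(diff(timepoints) <= 0)) {
    abort("`timepoints` must be positive and increasing.")
  }
  if (cv < 0) abort("`cv` must be >= 0.")
  set.seed(as.integer(seed))
  eps <- if (cv > 0) rnorm(length(timepoints), 0, cv) else numeric(length(timepoints))
  pct <- 100 * weibull_fdiss(timepoints, truth) * exp(eps)
  tibble(time_h = timepoints, dissolved_pct = pmin(pmax(pct, 0), 105))
}

#' Pseudo-observed PK data
#'
#' Adds multiplicative log-normal residual error to a simulated "true"
#' concentration--time profile and summarizes the noisy profile with the
#' same NCA machinery used for simulated trials, producing the
#' observed-summary table that [fold_assessment()] consumes. With `cv = 0`
#' the fold report against the generating simulation is identically 1.
#'
#' @param true_profile Tibble `time_h`, `conc` (the generating profile).
#' @param sampling_times Times (h) at which the pseudo-observations are
#'   taken; defaults to the profile's own times.
#' @param cv Residual error CV (>= 0).
#' @param seed Integer seed.
#' @param dosing_interval Passed to [nca_metrics()].
#' @return A list with `profile` (noisy tibble) and `observed` (tibble
#'   `metric`, `value` of Cmax/Tmax/AUCs, NCA-derived).
#' @export
gen_observed_pk <- function(true_profile, sampling_times = NULL, cv = 0,
                            seed = 1, dosing_interval = 24) {
  stopifnot(all(c("time_h", "conc") %in% names(true_profile)))
  if (cv < 0) abort("`cv` must be >= 0.")
  if (is.null(sampling_times)) {
    prof <- as_tibble(true_profile[c("time_h", "conc")])
  } else {
    f <- approxfun(true_profile$time_h, true_profile$conc, rule = 2)
    prof <- tibble(time_h = sampling_times, conc = f(sampling_times))
  }
  set.seed(as.integer(seed))
  eps <- if (cv > 0) rnorm(nrow(prof), 0, cv) else numeric(nrow(prof))
  prof$conc <- prof$conc * exp(eps)
  m <- nca_metrics(prof, dosing_interval = dosing_interval)
  observed <- tibble(
    metric = c("cmax", "tmax", "auc_0_tau", "auc_0_inf"),
    value = c(m$cmax, m$tmax, m$auc_0_tau, m$auc_0_inf))
  list(profile = prof, observed = observed)
}

#' Synthetic microsomal depletion data
#'
#' Exponential substrate-depletion curves whose observed rate scales with
#' the incubation unbound fraction: `conc = c0 * exp(-fu_inc * k_int * t)`
#' times multiplicative log-normal noise. Feeds [fit_fu_inc()].
#'
#' @param fu_inc_truth Ground-truth unbound fraction, (0, 1].
#' @param k_int Intrinsic depletion constant at `fu_inc = 1` (1/h).
#' @param timepoints Incubation sampling times (h).
#' @param c0 Initial substrate concentration.
#' @param cv Noise CV (>= 0).
#' @param seed Integer seed.
#' @return A tibble `time_h`, `conc`.
#' @export
gen_incubation_data <- function(fu_inc_truth, k_int = 2, timepoints = seq(0, 1, 0.1),
                                c0 = 1, cv = 0, seed = 1) {
  if (fu_inc_truth <= 0 || fu_inc_truth > 1) abort("`fu_inc_truth` must be in (0, 1].")
  if (k_int <= 0 || c0 <= 0 || cv < 0) abort("Invalid kinetic/noise settings.")
  set.seed(as.integer(seed))
  eps <- if (cv > 0) rnorm(length(timepoints), 0, cv) else numeric(length(timepoints))
  tibble(time_h = timepoints,
         conc = c0 * exp(-fu_inc_truth * k_int * timepoints) * exp(eps))
}
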
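# Shared fixtures: small, fast configurations used across test files.

ref_weibull <- function() weibull_params(33.70, 1.33)

# 24-h prolonged-release reference (8 mg study arm)
mr_weibull <- function() weibull_params(26.55, 1.22)

ropi_absorption <- function(peff = predict_peff(26.8)) {
  absorption_params(gut_geometry(), peff = peff,
                    fu_gut = fu_gut_rodgers_rowland(drug_ropinirole()))
}

# single-dose trial small enough for routine testing
small_trial_config <- function(dose_mg = 8, n = 2, n_doses = 1, ...) {
  trial_config(study_id = "test", population = "general_nec", n = n,
               age_range = c(47, 81), male_fraction = 0.5,
               weibull = mr_weibull(),
               regimen = tibble::tibble(dose_mg = dose_mg, interval_h = 24,
                                        n_doses = as.integer(n_doses)),
               followup_h = 48, ...)
}

# a geometry that collapses the nine-compartment system to one absorbing
# segment: instant gastric hand-off, no transit out of si1, negligible
# enterocyte residence -- the first-order absorption limit
single_segment_geometry <- function() {
  g <- gut_geometry()
  g$mrt_h <- c(1e-6, 1e9, rep(1e9, 6), 1e9)
  g$vent_L <- rep(1e-4, 9)
  g$qent_Lh <- rep(100, 9)
  g
}
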
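#' Virtual population specifications
#'
#' Three transparent population specs emulate the kinds of virtual
#' populations used for trial simulation: `healthy_adult` (phase-I style
#' volunteers), `general_nec` (a general North-European-Caucasian adult
#' population, used in place of a disease population) and `geriatric_nec`
#' (the same population carried into old age). They share a common
#' structure: log-normal body weight by sex, organ volumes scaling linearly
#' and blood flows allometrically (exponent 0.75) with weight, log-normal
#' liver mass, MPPGL and enzyme-abundance multipliers, and documented
#' age-related declines beyond age 40 (liver mass -0.5 %/yr, hepatic and
#' systemic blood flows -0.3 %/yr). The specs differ only in default age
#' ranges and body-weight means; they do not attempt to reproduce any
#' proprietary population library.
#'
#' @param name One of `"healthy_adult"`, `"general_nec"`,
#'   `"geriatric_nec"`.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(name = c("healthy_adult", "general_nec", "geriatric_nec")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    age_range = c(18, 50),
    male_fraction = 0.5,
    weight_mean = c(M = 80, F = 66),   # kg
    weight_cv = 0.16,
    liver_base_g = 1650,               # at 70 kg, age <= 40
    liver_cv = 0.20,
    mppgl_mean = 40, mppgl_cv = 0.30,
    clint_cv = 0.35,
    liver_age_slope = 0.005,           # fractional loss per year beyond 40
    flow_age_slope = 0.003,
    age_knee = 40
  )
  if (name == "general_nec") base$age_range <- c(20, 90)
  if (name == "geriatric_nec") base$age_range <- c(65, 98)
  validate_population_spec(base)
  structure(base, class = "population_spec")
}

validate_population_spec <- function(spec) {
  cvs <- c(spec$weight_cv, spec$liver_cv, spec$mppgl_cv, spec$clint_cv)
  if (any(cvs < 0)) abort("CVs must be non-negative.", class = "ropipbpk_spec_error")
  if (diff(spec$age_range) <= 0) abort("Age range must be non-degenerate.",
                                       class = "ropipbpk_spec_error")
  if (any(c(spec$weight_mean, spec$liver_base_g, spec$mppgl_mean) <= 0)) {
    abort("Mean physiological quantities must be positive.",
          class = "ropipbpk_spec_error")
  }
  invisible(spec)
}

# Log-normal draw with mean `m`, coefficient of variation `cv`, truncated
# at +/- 3 SD on the log scale.
rlnorm_trunc <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  z <- rnorm(n)
  z <- pmin(pmax(z, -3), 3)
  exp(meanlog + sdlog * z)
}

#' Sample one virtual subject
#'
#' Draws demographics and physiology from a population spec. Sampling is
#' fully deterministic given `seed`. Age-related declines (liver mass,
#' hepatic and systemic blood flow) apply beyond the spec's knee age.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed for this subject.
#' @param age_range Optional override of the spec's age range.
#' @param sex Optional fixed sex (`"M"`/`"F"`); sampled from the spec's
#'   male fraction otherwise.
#' @param subject_id Identifier stored in the subject row.
#'
#' @return A one-row `virtual_subject` tibble.
#' @export
sample_subject <- function(spec, seed, age_range = NULL, sex = NULL,
                           subject_id = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  validate_population_spec(spec)
  age_range <- age_range %||% spec$age_range
  if (diff(range(age_range)) < 0) abort("Invalid age range.", class = "ropipbpk_spec_error")
  set.seed(as.integer(seed))
  age <- runif(1, age_range[1], age_range[2])
  if (is.null(sex)) sex <- if (runif(1) < spec$male_fraction) "M" else "F"
  weight <- rlnorm_trunc(1, spec$weight_mean[[sex]], spec$weight_cv)
  yrs <- max(age - spec$age_knee, 0)
  age_liver <- (1 - spec$liver_age_slope)^yrs
  age_flow <- (1 - spec$flow_age_slope)^yrs
  vol_scale <- weight / 70
  flow_scale <- (weight / 70)^0.75 * age_flow
  liver_g <- rlnorm_trunc(1, spec$liver_base_g * vol_scale * age_liver, spec$liver_cv)
  mppgl <- rlnorm_trunc(1, spec$mppgl_mean, spec$mppgl_cv)
  clint_mult <- rlnorm_trunc(1, 1, spec$clint_cv)
  new_subject(subject_id = subject_id, age = age, sex = sex,
              weight_kg = weight, liver_g = liver_g, mppgl = mppgl,
              vol_scale = vol_scale, flow_scale = flow_scale,
              clint_mult = clint_mult)
}

#' Generate a virtual cohort
#'
#' Draws `n` subjects with the requested male:female split (rounded male
#' count, assigned deterministically before sampling). One global seed
#' yields a per-subject seed sequence (drawn once with `sample.int`), so a
#' cohort is reproducible subject-by-subject and extending `n` leaves
#' earlier subjects unchanged.
#'
#' @param spec A [population_spec()].
#' @param n Number of subjects, >= 1.
#' @param male_fraction Fraction of males (rounded to a count).
#' @param age_range Age range (years), inclusive bounds.
#' @param seed Global integer seed.
#'
#' @return A `virtual_subject` tibble with `n` rows.
#' @examples
#' cohort <- generate_cohort(population_spec("general_nec"), n = 5,
#'                           male_fraction = 0.6, age_range = c(47, 81),
#'                           seed = 1)
#' @export
generate_cohort <- function(spec, n, male_fraction = NULL, age_range = NULL,
                            seed = 1) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1.", class = "ropipbpk_spec_error")
  n <- as.integer(n)
  male_fraction <- male_fraction %||% spec$male_fraction
  n_male <- round(n * male_fraction)
  sexes <- c(rep("M", n_male), rep("F", n - n_male))
  set.seed(as.integer(seed))
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  rows <- purrr::map(seq_len(n), function(i) {
    sample_subject(spec, seed = subj_seeds[i], age_range = age_range,
                   sex = sexes[i], subject_id = i)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("virtual_subject", class(tibble()))
  out
}

#' Export a cohort to CSV
#'
#' Writes the standard cohort exchange columns
#' `subject_id,age,sex,weight_kg,liver_g,mppgl,qh_Lh`.
#'
#' @param cohort A `virtual_subject` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("subject_id", "age", "sex", "weight_kg", "liver_g", "mppgl", "qh_Lh")
  write.csv(as.data.frame(cohort)[cols], path, row.names = FALSE)
  invisible(path)
}
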
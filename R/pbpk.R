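#' Reference virtual subject
#'
#' A 70-kg reference adult with the default organ volumes/flows, liver mass
#' 1650 g, MPPGL 40 mg/g and total hepatic blood inflow 90 L/h (hepatic
#' artery + portal drainage of gut and spleen). Population sampling rescales
#' these (see [sample_subject()]).
#'
#' @return A one-row tibble of class `virtual_subject`.
#' @export
reference_subject <- function() {
  new_subject(subject_id = 1L, age = 35, sex = "M", weight_kg = 70,
              liver_g = 1650, mppgl = 40, vol_scale = 1, flow_scale = 1,
              clint_mult = 1)
}

new_subject <- function(subject_id, age, sex, weight_kg, liver_g, mppgl,
                        vol_scale, flow_scale, clint_mult) {
  out <- tibble(subject_id = as.integer(subject_id), age = age, sex = sex,
                weight_kg = weight_kg, liver_g = liver_g, mppgl = mppgl,
                vol_scale = vol_scale, flow_scale = flow_scale,
                clint_mult = clint_mult,
                qh_Lh = 90 * flow_scale)
  class(out) <- c("virtual_subject", class(out))
  out
}

#' Scaled organ volumes and blood flows for a subject
#'
#' Volumes scale linearly with body weight; flows scale with the subject's
#' flow factor (allometric weight scaling times the age-related decline
#' applied by the population sampler). The liver volume is taken from the
#' sampled liver mass at unit density.
#'
#' @param subject A `virtual_subject` row.
#' @return A tibble `organ`, `volume_L`, `flow_Lh`.
#' @export
subject_physiology <- function(subject) {
  org <- organ_reference()
  org$volume_L <- org$volume_L * subject$vol_scale
  org$flow_Lh <- org$flow_Lh * subject$flow_scale
  org$volume_L[org$organ == "liver"] <- subject$liver_g / 1000
  org
}

pbpk_organs <- c("adipose", "bone", "brain", "gut", "heart", "kidney",
                 "liver", "lung", "muscle", "skin", "spleen")

#' Assemble PBPK parameters for one subject
#'
#' Precomputes everything the whole-body right-hand side needs: plasma-
#' referenced partition coefficients from the Rodgers--Rowland method,
#' scaled organ volumes and flows, the IVIVE unbound intrinsic hepatic
#' clearance (times the subject's enzyme-abundance multiplier), and the
#' permeability-derived segmental absorption constants.
#'
#' @param drug A [drug_properties()] object.
#' @param subject A `virtual_subject` row, default [reference_subject()].
#' @param geometry Gut geometry, see [gut_geometry()].
#' @param perm_config Permeability correlations,
#'   [default_permeability_config()].
#' @param renal_cl Renal plasma clearance (L/h); 0 for ropinirole
#'   (hepatic elimination only), exposed as a hook.
#'
#' @return A list of model constants consumed by [simulate_profile()].
#' @export
make_pbpk_params <- function(drug, subject = reference_subject(),
                             geometry = gut_geometry(),
                             perm_config = default_permeability_config(),
                             renal_cl = 0) {
  stopifnot(inherits(drug, "drug_properties"))
  kpu <- kpu_rodgers_rowland(drug)
  phys <- subject_physiology(subject)
  v <- setNames(phys$volume_L, phys$organ)
  q <- setNames(phys$flow_Lh, phys$organ)
  kp <- setNames(kpu$kp, kpu$tissue)
  missing <- setdiff(pbpk_organs, names(kp))
  if (length(missing)) {
    abort(sprintf("Partition table lacks organ(s): %s", paste(missing, collapse = ", ")),
          class = "ropipbpk_configuration_error")
  }
  clu_int <- if (!is.null(drug$pathways)) {
    ivive_hepatic_clint(drug$pathways, fu_mic = drug$fu_mic,
                        mppgl = subject$mppgl, liver_g = subject$liver_g) *
      subject$clint_mult
  } else 0
  peff <- if (is.finite(drug$papp_pampa)) predict_peff(drug$papp_pampa, perm_config) else 0
  absorption <- absorption_params(geometry, peff = peff,
                                  fu_gut = fu_gut_rodgers_rowland(drug))
  co <- sum(q[setdiff(pbpk_organs, "lung")])
  list(drug = drug, subject = subject, v = v, q = q, kp = kp,
       kpu_liver = kpu$kpu[kpu$tissue == "liver"],
       clu_int = clu_int, renal_cl = renal_cl, co = co,
       q_liver_total = q[["liver"]] + q[["gut"]] + q[["spleen"]],
       absorption = absorption, peff = peff,
       # flat vectors in pbpk_state_template() order for the solver loop
       vv = unname(v[pbpk_organs]), qq = unname(q[pbpk_organs]),
       kpv = unname(kp[pbpk_organs]),
       v_art = v[["arterial"]], v_ven = v[["venous"]])
}

pbpk_state_template <- function() {
  nm <- c(paste0("a_", pbpk_organs), "a_art", "a_ven", "eliminated")
  setNames(numeric(length(nm)), nm)
}

# Whole-body perfusion-limited balances (venous-equilibrium convention).
# `gut_flux` is the mg/h absorption input delivered to the liver via the
# portal vein. Amounts mg, volumes L, flows L/h; bp converts plasma- to
# blood-referenced concentrations. Integer-indexed (state order fixed by
# pbpk_state_template()) because this sits in the solver's inner loop.
# Organ indices: 1 adipose, 2 bone, 3 brain, 4 gut, 5 heart, 6 kidney,
# 7 liver, 8 lung, 9 muscle, 10 skin, 11 spleen; then 12 arterial,
# 13 venous, 14 cumulative eliminated.
pbpk_rhs_core <- function(t, y, p, gut_flux = 0) {
  bp <- p$drug$bp
  c_t <- y[1:11] / p$vv                  # tissue concentration (mg/L)
  cv_t <- c_t * bp / p$kpv               # emergent venous blood conc
  c_art <- y[12] / p$v_art
  c_ven <- y[13] / p$v_ven

  periph <- c(1L, 2L, 3L, 5L, 6L, 9L, 10L)
  d <- numeric(14)
  d[periph] <- p$qq[periph] * (c_art - cv_t[periph])
  d[4] <- p$qq[4] * (c_art - cv_t[4])    # gut
  d[11] <- p$qq[11] * (c_art - cv_t[11]) # spleen

  elim_hep <- p$clu_int * c_t[7] / p$kpu_liver
  d[7] <- p$qq[7] * c_art + p$qq[4] * cv_t[4] + p$qq[11] * cv_t[11] +
    gut_flux - p$q_liver_total * cv_t[7] - elim_hep

  elim_ren <- p$renal_cl * cv_t[6] / bp  # plasma clearance hook
  d[6] <- d[6] - elim_ren

  d[13] <- sum(p$qq[periph] * cv_t[periph]) +
    p$q_liver_total * cv_t[7] - p$co * c_ven
  d[8] <- p$co * (c_ven - cv_t[8])
  d[12] <- p$co * cv_t[8] - p$co * c_art
  d[14] <- elim_hep + elim_ren
  d
}

#' Simulate a plasma concentration profile for one subject
#'
#' Couples the nine-compartment gut model to the whole-body PBPK model in a
#' single ODE system: the Weibull release rate feeds the lumen, absorbed
#' drug leaves the enterocytes with the villous blood flow and enters the
#' liver through the portal vein. Repeated dosing (including titration
#' phases) is handled with solver events that drop each tablet into the
#' stomach at its administration time.
#'
#' @param subject A `virtual_subject` row.
#' @param drug A [drug_properties()] object.
#' @param weibull Release parameters, [weibull_params()].
#' @param regimen A regimen tibble, see [regimen_qd()]. Ignored when
#'   `dose_schedule` is given.
#' @param dose_schedule Optional explicit tibble `time_h`, `amount_mg`.
#' @param t_end End of integration (h); default runs 48 h past the last
#'   dose.
#' @param dt_out Output resolution (h).
#' @param prandial Prandial state, affects gastric residence only.
#' @param geometry Optional gut geometry override.
#' @param rtol,atol Solver tolerances.
#' @param check_mass_balance Assert whole-body conservation (default TRUE).
#'
#' @return An object of class `pk_profile`: tibble `time_h`, `conc`
#'   (venous plasma, ug/L) plus the full state matrix, parameters and the
#'   dose schedule as attributes.
#' @export
simulate_profile <- function(subject, drug, weibull, regimen = NULL,
                             dose_schedule = NULL, t_end = NULL,
                             dt_out = 0.25, prandial = c("fasted", "fed"),
                             geometry = NULL, rtol = 1e-8, atol = 1e-10,
                             check_mass_balance = TRUE) {
  prandial <- match.arg(prandial)
  if (is.null(geometry)) geometry <- gut_geometry(prandial = prandial)
  if (is.null(dose_schedule)) {
    if (is.null(regimen)) abort("Provide `regimen` or `dose_schedule`.")
    dose_schedule <- regimen_schedule(regimen)
  }
  if (any(dose_schedule$amount_mg < 0)) abort("Doses must be non-negative.")
  if (is.null(t_end)) t_end <- max(dose_schedule$time_h) + 48

  p <- make_pbpk_params(drug, subject, geometry = geometry)
  zero_dose <- all(dose_schedule$amount_mg == 0)
  gp <- build_gut_params(weibull, p$absorption,
                         doses = dose_schedule[dose_schedule$amount_mg > 0, , drop = FALSE])
  if (nrow(gp$doses) == 0) gp$doses <- tibble(time_h = Inf, amount_mg = 0)

  y0 <- c(gut_state_template(), pbpk_state_template())
  ngut <- length(gut_state_template())
  qent <- p$absorption$geometry$qent_Lh
  ce_idx <- 3 * 9 + 1:9

  rhs <- function(t, y, parms) {
    yg <- y[1:ngut]
    dg <- gut_rhs_core(t, yg, gp)
    flux <- sum(qent * yg[ce_idx])
    # absorbed drug leaves the enterocytes into the portal vein -> liver
    ds <- pbpk_rhs_core(t, y[-(1:ngut)], p, gut_flux = flux)
    list(c(dg, ds))
  }

  times <- sort(unique(c(seq(0, t_end, by = dt_out), t_end,
                         dose_schedule$time_h[dose_schedule$time_h <= t_end])))
  ev <- NULL
  if (!zero_dose) {
    y0[["af1"]] <- sum(gp$doses$amount_mg[gp$doses$time_h == 0])
    dd <- gp$doses[gp$doses$time_h > 0 & gp$doses$time_h <= t_end, , drop = FALSE]
    if (nrow(dd)) {
      ev <- list(data = data.frame(var = "af1", time = dd$time_h,
                                   value = dd$amount_mg, method = "add"))
    }
  }
  sol <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                        events = ev, rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    abort("PBPK integration failed.", class = "ropipbpk_integration_failure",
          last_state = sol[nrow(sol), ])
  }
  states <- as_tibble(as.data.frame(sol)) |> rename(time_h = "time")
  conc <- states$a_ven / p$v[["venous"]] / drug$bp * 1000  # ug/L plasma
  out <- tibble(time_h = states$time_h, conc = pmax(conc, 0))
  if (check_mass_balance && !zero_dose) {
    mb <- profile_mass_balance(states, gp, p, dose_schedule)
    worst <- max(abs(mb$rel_error))
    if (worst > 1e-3) {
      abort(sprintf("Mass-balance violation: max relative error %.3g.", worst),
            class = "ropipbpk_mass_balance_error")
    }
  }
  structure(out, states = states, params = p, gut_params = gp,
            dose_schedule = dose_schedule,
            class = c("pk_profile", class(out)))
}

profile_mass_balance <- function(states, gp, p, dose_schedule) {
  ce <- as.matrix(states[paste0("ce", 1:9)])
  gut_total <- rowSums(states[paste0("af", 1:9)]) +
    rowSums(states[paste0("as", 1:9)]) + rowSums(states[paste0("ad", 1:9)]) +
    as.numeric(ce %*% gp$vent)
  body_total <- rowSums(states[paste0("a_", pbpk_organs)]) +
    states$a_art + states$a_ven
  total <- gut_total + body_total + states$feces + states$degraded +
    states$gut_met + states$eliminated
  # an output row recorded exactly at an event time precedes the event, so
  # doses administered at t > 0 count only strictly before the row's time
  dosed <- purrr::map_dbl(states$time_h, function(t) {
    sum(dose_schedule$amount_mg[dose_schedule$time_h < t |
                                  dose_schedule$time_h == 0])
  })
  tibble(time_h = states$time_h, total_mg = total, dosed_mg = dosed,
         rel_error = ifelse(dosed > 0, (total - dosed) / dosed, 0))
}

#' Simulate an intravenous bolus
#'
#' Runs the systemic model alone with the dose placed in venous blood at
#' time zero; used for characterizing distribution/elimination without
#' absorption (for example terminal-slope checks).
#'
#' @inheritParams simulate_profile
#' @param dose_mg IV dose (mg).
#' @return A `pk_profile` tibble (`time_h`, `conc` in ug/L plasma).
#' @export
simulate_iv_bolus <- function(subject, drug, dose_mg, t_end = 48,
                              dt_out = 0.1, rtol = 1e-8, atol = 1e-10) {
  p <- make_pbpk_params(drug, subject)
  y0 <- pbpk_state_template()
  y0[["a_ven"]] <- dose_mg
  sol <- deSolve::lsoda(
    y = y0, times = seq(0, t_end, by = dt_out),
    func = function(t, y, parms) list(pbpk_rhs_core(t, y, p)),
    parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort("PBPK integration failed.", class = "ropipbpk_integration_failure")
  }
  states <- as_tibble(as.data.frame(sol)) |> rename(time_h = "time")
  out <- tibble(time_h = states$time_h,
                conc = states$a_ven / p$v[["venous"]] / drug$bp * 1000)
  structure(out, states = states, params = p,
            class = c("pk_profile", class(out)))
}
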
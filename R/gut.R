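#' Gastrointestinal geometry and transit defaults
#'
#' Nine anatomical compartments: stomach, seven small-intestine (SI)
#' segments, colon. Drug movement between compartments is first-order with
#' rate `1/mrt_h`. Defaults: fasted gastric residence 0.4 h (1.0 h fed), SI
#' total residence `si_transit_h` (default 3.3 h) split across the seven
#' segments in proportion to anatomical length, colonic residence 12 h.
#' Radii taper from the duodenum to the ileum around the jejunal reference
#' of 1.75 cm. Enterocyte volumes and villous blood flows are split across
#' the SI proportional to length. The stomach's relative-absorption scalar
#' is 0 (no gastric absorption); the colon's defaults to 1, appropriate for
#' a freely permeable base.
#'
#' @param prandial `"fasted"` or `"fed"`; fed state only lengthens gastric
#'   residence (the package's reduced food-effect model).
#' @param stomach_mrt_h Override gastric mean residence time (h).
#' @param si_transit_h Total small-intestinal transit time (h).
#' @param colon_mrt_h Colonic mean residence time for fluid/dissolved drug (h).
#' @param colon_rel_abs Relative-absorption scalar for the colon.
#'
#' @return A tibble with one row per segment: `segment`, `mrt_h`,
#'   `radius_cm`, `vent_L` (enterocyte volume), `qent_Lh` (enterocyte blood
#'   flow), `rel_abs`.
#' @export
gut_geometry <- function(prandial = c("fasted", "fed"), stomach_mrt_h = NULL,
                         si_transit_h = 3.3, colon_mrt_h = 12,
                         colon_rel_abs = 1) {
  prandial <- match.arg(prandial)
  if (is.null(stomach_mrt_h)) {
    stomach_mrt_h <- if (prandial == "fasted") 0.4 else 1.0
  }
  stopifnot(stomach_mrt_h > 0, si_transit_h > 0, colon_mrt_h > 0)
  rel_len <- c(0.05, 0.13, 0.17, 0.17, 0.17, 0.16, 0.15)  # duodenum -> ileum
  tibble(
    segment  = c("stomach", paste0("si", 1:7), "colon"),
    mrt_h    = c(stomach_mrt_h, si_transit_h * rel_len, colon_mrt_h),
    radius_cm = c(10, 2.0, 1.75, 1.75, 1.5, 1.5, 1.25, 1.25, 2.5),
    vent_L   = c(0.01, 0.25 * rel_len, 0.05),
    qent_Lh  = c(0.5, 27 * rel_len, 3),
    rel_abs  = c(0, rep(1, 7), colon_rel_abs)
  )
}

#' Segmental absorption parameters
#'
#' Assembles the per-segment rate constants of the gut model: absorption
#' (`ka`, from the permeability chain via [segmental_ka()]), luminal
#' degradation, enterocyte efflux and gut metabolic clearances, and the
#' fraction unbound in the enterocyte. The ropinirole configuration sets
#' degradation, efflux and gut metabolism to zero (passive absorption, no
#' transporters, CYP1A2 absent from the gut wall).
#'
#' @param geometry Gut geometry tibble, see [gut_geometry()].
#' @param peff Effective permeability (1e-4 cm/s).
#' @param fu_gut Fraction unbound in the enterocyte, (0, 1].
#' @param kdeg Luminal degradation constant (1/h), scalar or per segment.
#' @param clu_int_t,clu_int_g Unbound efflux / gut metabolic clearances
#'   (L/h), scalar or per segment.
#' @param gamma Unit-adjustment factor for effluxed drug.
#'
#' @return A list with the geometry and per-segment rate vectors.
#' @export
absorption_params <- function(geometry = gut_geometry(), peff,
                              fu_gut = 1, kdeg = 0, clu_int_t = 0,
                              clu_int_g = 0, gamma = 1) {
  if (fu_gut <= 0 || fu_gut > 1) abort("`fu_gut` must be in (0, 1].")
  n <- nrow(geometry)
  geom_ka <- segmental_ka(peff, geometry)
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else {stopifnot(length(x) == n); x}
  list(geometry = geometry, ka = geom_ka$ka, kdeg = rep_n(kdeg),
       clu_int_t = rep_n(clu_int_t), clu_int_g = rep_n(clu_int_g),
       fu_gut = fu_gut, gamma = gamma)
}

# Indices into the gut state vector (shared by the standalone and the
# coupled simulators). n segments = 9; order: stomach, si1..si7, colon.
gut_state_template <- function() {
  nm <- c(paste0("af", 1:9), paste0("as", 1:9), paste0("ad", 1:9),
          paste0("ce", 1:9), "absorbed", "feces", "degraded", "gut_met")
  setNames(numeric(length(nm)), nm)
}

# Right-hand side of the nine-compartment gut system. `p` carries:
# geometry-derived vectors (kt, vent, qent), absorption params, the Weibull
# release object (plus flattened copies of its parameters and the dose
# schedule for speed -- this sits in the solver's inner loop), and switches
# bypass_solid / k_diss / formulation_exits_colon.
gut_rhs_core <- function(t, y, p) {
  n <- 9
  af <- y[1:n]; as_ <- y[n + 1:n]; ad <- y[2 * n + 1:n]; ce <- y[3 * n + 1:n]
  kt <- p$kt; ka <- p$ka

  # formulation release, distributed across segments by formulation mass;
  # Weibull rate inlined: rate_i = fmax * beta * tau^(beta-1)/alpha * e^(-tau^beta/alpha)
  tot_af <- sum(af)
  rate <- 0
  expected_left <- p$total_dose
  if (tot_af > 1e-12) {
    act <- p$dose_times < t
    if (any(act)) {
      tau <- t - p$dose_times[act]
      if (p$wb_beta < 1) tau <- pmax(tau, 1e-6)  # capped singular derivative
      tb <- tau^p$wb_beta
      ee <- exp(-tb / p$wb_alpha)
      amt <- p$dose_amts[act]
      rate <- sum(amt * ee * tb / tau) * p$wb_fmax * p$wb_beta / p$wb_alpha
      if (p$formulation_exits_colon) {
        expected_left <- p$total_dose - p$wb_fmax * sum(amt * (1 - ee))
      }
    }
  }
  if (tot_af > 1e-12 && rate > 0) {
    scale <- if (p$formulation_exits_colon && expected_left > 1e-12) {
      min(tot_af / expected_left, 1)
    } else 1
    rel_n <- rate * scale * af / tot_af
  } else {
    rel_n <- numeric(n)
  }

  # transit of the intact formulation (monolith retained in colon by default)
  kt_f <- p$kt_f
  daf <- -rel_n - kt_f * af + c(0, (kt_f * af)[-n])

  if (p$bypass_solid) {
    rel_solid <- numeric(n); rel_diss <- rel_n
    diss <- numeric(n)
  } else {
    rel_solid <- rel_n; rel_diss <- numeric(n)
    diss <- p$k_diss * as_
  }
  das <- rel_solid - diss - kt * as_ + c(0, (kt * as_)[-n])
  dad <- rel_diss + diss - (p$kdeg + ka + kt) * ad + c(0, (kt * ad)[-n]) +
    p$gamma * p$clu_int_t * p$fu_gut * ce
  dce <- (ad * ka - ce * p$qent - p$fu_gut * ce * (p$clu_int_g + p$clu_int_t)) / p$vent

  dabsorbed <- sum(p$qent * ce)
  dfeces <- kt[n] * (ad[n] + as_[n]) + kt_f[n] * af[n]
  ddegraded <- sum(p$kdeg * ad)
  dgut_met <- sum(p$fu_gut * ce * p$clu_int_g)

  c(daf, das, dad, dce, dabsorbed, dfeces, ddegraded, dgut_met)
}

build_gut_params <- function(weibull, absorption, doses,
                             bypass_solid = TRUE, k_diss = 50,
                             formulation_exits_colon = FALSE) {
  geom <- absorption$geometry
  wb <- as_weibull_params(weibull)
  list(kt = 1 / geom$mrt_h, vent = geom$vent_L, qent = geom$qent_Lh,
       ka = absorption$ka, kdeg = absorption$kdeg,
       clu_int_t = absorption$clu_int_t, clu_int_g = absorption$clu_int_g,
       fu_gut = absorption$fu_gut, gamma = absorption$gamma,
       weibull = wb, doses = doses,
       # flattened for the solver's inner loop
       wb_alpha = wb$alpha, wb_beta = wb$beta, wb_fmax = wb$fmax,
       wb_lag = wb$lag,
       dose_times = doses$time_h + wb$lag, dose_amts = doses$amount_mg,
       total_dose = sum(doses$amount_mg),
       kt_f = (1 / geom$mrt_h) * c(rep(1, 8), as.numeric(formulation_exits_colon)),
       bypass_solid = bypass_solid, k_diss = k_diss,
       formulation_exits_colon = formulation_exits_colon)
}

#' Simulate gastrointestinal transit, release and absorption
#'
#' Integrates the nine-compartment gut system for one or more oral doses of
#' the modified-release formulation. Release from the dosage form follows
#' the Weibull rate (the rate-limiting step for this product); released
#' drug is treated as instantaneously dissolved by default
#' (`bypass_solid = TRUE`), or can be routed through the solid pool with a
#' fast intrinsic dissolution constant. The intact monolith is retained in
#' the colon by default (`formulation_exits_colon = FALSE`); dissolved drug
#' always transits out of the colon to feces.
#'
#' @param dose_mg Dose per administration (mg), > 0.
#' @param weibull Release parameters, [weibull_params()].
#' @param absorption Segmental absorption parameters, [absorption_params()].
#' @param t_end End of integration (h).
#' @param dose_times_h Administration times (h), default single dose at 0.
#' @param dt_out Output resolution (h).
#' @param bypass_solid Treat released drug as dissolved immediately.
#' @param k_diss Intrinsic dissolution constant (1/h) when
#'   `bypass_solid = FALSE`.
#' @param formulation_exits_colon Should intact formulation transit out of
#'   the colon?
#' @param rtol,atol Solver tolerances.
#'
#' @return An object of class `gut_sim`: a list with `states` (tibble of all
#'   compartment amounts over time), `flux` (tibble `time_h`,
#'   `flux_mg_per_h` of drug entering the portal vein), `fa` (fraction of
#'   the total dose absorbed by `t_end`) and the inputs.
#' @examples
#' ap <- absorption_params(gut_geometry(), peff = 5.01)
#' sim <- simulate_gut(8, weibull_params(26.55, 1.22), ap, t_end = 48)
#' sim$fa
#' @export
simulate_gut <- function(dose_mg, weibull, absorption, t_end,
                         dose_times_h = 0, dt_out = 0.25,
                         bypass_solid = TRUE, k_diss = 50,
                         formulation_exits_colon = FALSE,
                         rtol = 1e-8, atol = 1e-10) {
  if (!is.finite(dose_mg) || dose_mg <= 0) abort("`dose_mg` must be positive.")
  doses <- tibble(time_h = dose_times_h, amount_mg = dose_mg)
  p <- build_gut_params(weibull, absorption, doses, bypass_solid, k_diss,
                        formulation_exits_colon)
  y0 <- gut_state_template()
  # doses at t = 0 start in the stomach; later doses arrive as solver events
  y0[["af1"]] <- sum(doses$amount_mg[doses$time_h == 0])
  later <- doses[doses$time_h > 0, , drop = FALSE]
  ev <- if (nrow(later)) {
    list(data = data.frame(var = "af1", time = later$time_h,
                           value = later$amount_mg, method = "add"))
  } else NULL
  times <- sort(unique(c(seq(0, t_end, by = dt_out), t_end, doses$time_h)))
  sol <- deSolve::lsoda(
    y = y0, times = times,
    func = function(t, y, parms) list(gut_rhs_core(t, y, parms)),
    parms = p, events = ev, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort("Gut ODE integration failed; last valid state attached.",
          class = "ropipbpk_integration_failure",
          last_state = sol[nrow(sol), ])
  }
  states <- as_tibble(as.data.frame(sol)) |> rename(time_h = "time")
  if (any(as.matrix(states[-1]) < -1e-6 * sum(doses$amount_mg))) {
    abort("Negative compartment amounts beyond solver tolerance.",
          class = "ropipbpk_integration_failure")
  }
  qent <- absorption$geometry$qent_Lh
  ce_cols <- paste0("ce", 1:9)
  flux <- tibble(
    time_h = states$time_h,
    flux_mg_per_h = as.numeric(as.matrix(states[ce_cols]) %*% qent))
  total_dose <- sum(doses$amount_mg)
  structure(
    list(states = states, flux = flux,
         fa = states$absorbed[nrow(states)] / total_dose,
         dose_mg = total_dose, params = p),
    class = "gut_sim")
}

#' @export
print.gut_sim <- function(x, ...) {
  cat(sprintf("<gut_sim> total dose %.3g mg; fa = %.4f at t = %.3g h\n",
              x$dose_mg, x$fa, max(x$states$time_h)))
  invisible(x)
}

#' Mass balance of a gut simulation
#'
#' Sums formulation, solid, dissolved, enterocyte, absorbed, fecal,
#' degraded and gut-metabolized drug at every output time; for a closed
#' system this must equal the administered dose (so far) at all times.
#'
#' @param sim A `gut_sim` object.
#' @return A tibble `time_h`, `total_mg`, `dosed_mg`, `rel_error`.
#' @export
gut_mass_balance <- function(sim) {
  st <- sim$states
  vent <- sim$params$vent
  ce <- as.matrix(st[paste0("ce", 1:9)])
  total <- rowSums(st[paste0("af", 1:9)]) + rowSums(st[paste0("as", 1:9)]) +
    rowSums(st[paste0("ad", 1:9)]) + as.numeric(ce %*% vent) +
    st$absorbed + st$feces + st$degraded + st$gut_met
  # rows at an event time precede the event: later doses count strictly
  dosed <- purrr::map_dbl(st$time_h, function(t) {
    sum(sim$params$doses$amount_mg[sim$params$doses$time_h < t |
                                     sim$params$doses$time_h == 0])
  })
  tibble(time_h = st$time_h, total_mg = total, dosed_mg = dosed,
         rel_error = ifelse(dosed > 0, (total - dosed) / dosed, 0))
}

#' Write the portal-vein flux series of a gut simulation to CSV
#'
#' @param sim A `gut_sim` object.
#' @param path Output path; header `time_h,flux_mg_per_h`.
#' @return `path`, invisibly.
#' @export
write_gut_flux_csv <- function(sim, path) {
  write.csv(sim$flux, path, row.names = FALSE)
  invisible(path)
}
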
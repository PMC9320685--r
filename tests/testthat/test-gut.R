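test_that("the empty gut has a zero derivative", {
  ap <- ropi_absorption()
  p <- ropipbpk:::build_gut_params(mr_weibull(), ap,
                                   doses = tibble::tibble(time_h = Inf, amount_mg = 0))
  y0 <- ropipbpk:::gut_state_template()
  expect_true(all(ropipbpk:::gut_rhs_core(2, y0, p) == 0))
})

test_that("mass balance closes to 0.1% of dose at every solver output", {
  sim <- simulate_gut(8, mr_weibull(), ropi_absorption(), t_end = 48)
  mb <- gut_mass_balance(sim)
  expect_lt(max(abs(mb$rel_error)), 1e-3)
  # and under multiple dosing
  sim2 <- simulate_gut(4, mr_weibull(), ropi_absorption(), t_end = 72,
                       dose_times_h = c(0, 24, 48))
  expect_lt(max(abs(gut_mass_balance(sim2)$rel_error)), 1e-3)
})

test_that("single-segment instantaneous-release limit matches first-order absorption", {
  # collapse to one absorbing segment; near-instant release (alpha tiny)
  g <- single_segment_geometry()
  ap <- absorption_params(g, peff = 5.01)
  ka <- ap$ka[2]  # si1
  sim <- simulate_gut(1, weibull_params(1e-6, 1), ap, t_end = 5, dt_out = 0.05)
  st <- sim$states[sim$states$time_h >= 0.5, ]
  expect_equal(st$ad2, exp(-ka * st$time_h), tolerance = 1e-5)
  # absorbed mass follows dose * (1 - e^(-ka t)) up to the (small)
  # enterocyte passage delay
  expect_equal(st$absorbed, 1 - exp(-ka * st$time_h), tolerance = 1e-4)
})

test_that("a high-permeability 24-h release product is nearly completely absorbed", {
  ap <- absorption_params(gut_geometry(), peff = 20)
  sim <- simulate_gut(8, mr_weibull(), ap, t_end = 48)
  expect_gte(sim$fa, 0.95)
})

test_that("zero permeability sends all released drug to feces", {
  ap <- absorption_params(gut_geometry(), peff = 0)
  sim <- simulate_gut(8, mr_weibull(), ap, t_end = 300)
  expect_equal(sim$fa, 0)
  st <- tail(sim$states, 1)
  expect_gt(st$feces / 8, 0.99)
})

test_that("fraction absorbed responds monotonically to permeability, transit and time", {
  fa <- vapply(c(1, 5, 20), function(pe) {
    simulate_gut(8, mr_weibull(), absorption_params(gut_geometry(), peff = pe),
                 t_end = 48)$fa
  }, numeric(1))
  expect_true(all(diff(fa) > 0))
  # absorbed amount is non-decreasing in time within one simulation
  sim <- simulate_gut(8, mr_weibull(), ropi_absorption(), t_end = 48)
  expect_true(all(diff(sim$states$absorbed) >= -1e-12))
  # faster transit everywhere lowers fa
  fast <- gut_geometry(si_transit_h = 1.65, colon_mrt_h = 6)
  sim_fast <- simulate_gut(8, mr_weibull(),
                           absorption_params(fast, peff = predict_peff(26.8)),
                           t_end = 48)
  expect_lt(sim_fast$fa, sim$fa)
})

test_that("zero elimination reproduces the reduced transit-absorption system", {
  # independent reduced RHS: transit + release + absorption only
  reduced_rhs <- function(t, y, p) {
    n <- 9
    af <- y[1:n]; as_ <- y[n + 1:n]; ad <- y[2 * n + 1:n]; ce <- y[3 * n + 1:n]
    tot <- sum(af)
    rate <- if (tot > 1e-12 && t > 0) {
      weibull_release_rate(t, p$weibull, dose = 1) * p$total_dose
    } else 0
    rel <- if (tot > 1e-12) rate * af / tot else numeric(n)
    daf <- -rel - p$kt_f * af + c(0, (p$kt_f * af)[-n])
    das <- -p$kt * as_ + c(0, (p$kt * as_)[-n])  # inert solids still transit
    dad <- rel - (p$ka + p$kt) * ad + c(0, (p$kt * ad)[-n])
    dce <- (ad * p$ka - ce * p$qent) / p$vent
    c(daf, das, dad, dce, sum(p$qent * ce),
      p$kt[n] * (ad[n] + as_[n]), 0, 0)
  }
  ap <- ropi_absorption()
  p <- ropipbpk:::build_gut_params(mr_weibull(), ap,
                                   doses = tibble::tibble(time_h = 0, amount_mg = 8))
  set.seed(99)
  for (i in 1:5) {
    y <- abs(rnorm(length(ropipbpk:::gut_state_template()), sd = 0.5))
    t <- runif(1, 0.1, 30)
    expect_equal(ropipbpk:::gut_rhs_core(t, y, p), reduced_rhs(t, y, p),
                 tolerance = 1e-12)
  }
})

test_that("gut simulations export the portal flux series", {
  sim <- simulate_gut(8, mr_weibull(), ropi_absorption(), t_end = 24)
  expect_true(all(sim$flux$flux_mg_per_h >= 0))
  # flux integrates to the absorbed amount
  fl <- sim$flux
  auc <- sum(diff(fl$time_h) * (head(fl$flux_mg_per_h, -1) + tail(fl$flux_mg_per_h, -1)) / 2)
  expect_equal(auc, tail(sim$states$absorbed, 1), tolerance = 1e-3)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_gut_flux_csv(sim, csv)
  expect_equal(names(read.csv(csv)), c("time_h", "flux_mg_per_h"))
})
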
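test_that("Weibull release curve matches closed-form arithmetic", {
  wb <- ref_weibull()
  expect_identical(weibull_fdiss(0, wb), 0)
  # direct evaluation of fmax*(1 - exp(-t^beta/alpha))
  expect_equal(weibull_fdiss(12, wb), 1 - exp(-12^1.33 / 33.70), tolerance = 1e-12)
  expect_equal(weibull_fdiss(12, wb), 0.5545, tolerance = 1e-3)
  expect_equal(weibull_fdiss(24, wb), 0.869, tolerance = 1e-3)
})

test_that("Fdiss is monotone, bounded by fmax and saturates", {
  for (pars in list(c(5, 0.8), c(33.7, 1.33), c(50, 2))) {
    wb <- weibull_params(pars[1], pars[2], fmax = 0.97, lag = 1)
    tt <- seq(0, 200, by = 0.5)
    f <- weibull_fdiss(tt, wb)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f <= wb$fmax + 1e-12))
    expect_true(all(f[tt <= wb$lag] == 0))
    expect_equal(weibull_fdiss(1e4, wb), wb$fmax, tolerance = 1e-6)
  }
})

test_that("invalid Weibull inputs are rejected", {
  expect_error(weibull_params(-1, 1), class = "ropipbpk_invalid_parameter")
  expect_error(weibull_params(10, 1, fmax = 1.2), class = "ropipbpk_invalid_parameter")
  expect_error(weibull_params(Inf, 1), class = "ropipbpk_invalid_parameter")
  expect_error(weibull_fdiss(NaN, ref_weibull()), class = "ropipbpk_invalid_parameter")
  expect_error(weibull_release_rate(1, ref_weibull(), dose = -2),
               class = "ropipbpk_invalid_parameter")
})

test_that("release rate is the derivative of dose * Fdiss", {
  wb <- ref_weibull()
  # exponential limit: beta = 1 gives rate dose/alpha at t = 0
  expect_equal(weibull_release_rate(0, weibull_params(10, 1), dose = 1), 0.1)
  # before the lag there is no release
  expect_identical(weibull_release_rate(0.5, weibull_params(10, 1.2, lag = 1), dose = 5), 0)
  # quadrature of the rate recovers dose * Fdiss
  q <- integrate(function(t) weibull_release_rate(t, wb, dose = 8),
                 0, 24, rel.tol = 1e-10)
  expect_equal(q$value, 8 * weibull_fdiss(24, wb), tolerance = 1e-6)
  # same under a sub-exponential shape with its singular t = lag derivative
  wb2 <- weibull_params(8, 0.85)
  expect_true(is.finite(weibull_release_rate(0, wb2, dose = 1)))
  q2 <- integrate(function(t) weibull_release_rate(t, wb2, dose = 3),
                  0, 48, rel.tol = 1e-9)
  expect_equal(q2$value, 3 * weibull_fdiss(48, wb2), tolerance = 1e-5)
})

test_that("noiseless points are refit to machine precision across the parameter range", {
  # sampling must straddle the rise of the curve for the parameters to be
  # identifiable: fast-release shapes (small alpha, large beta) saturate a
  # {2, 12, 24} h certificate grid, so the sweep uses a denser design
  tt <- c(0.5, 1, 2, 4, 8, 12, 18, 24)
  for (alpha in c(5, 20, 50)) {
    for (beta in c(0.8, 1.3, 2)) {
      pts <- tibble::tibble(
        time_h = tt,
        dissolved_pct = 100 * weibull_fdiss(tt, weibull_params(alpha, beta)))
      fit <- fit_weibull(pts)
      expect_true(fit$converged)
      expect_equal(fit$params$alpha, alpha, tolerance = 1e-6)
      expect_equal(fit$params$beta, beta, tolerance = 1e-6)
    }
  }
  # the three-point certificate grid still identifies 24-h release shapes
  for (pars in list(c(17.14, 1.08), c(26.55, 1.22), c(38.44, 1.35))) {
    pts <- tibble::tibble(
      time_h = c(2, 12, 24),
      dissolved_pct = 100 * weibull_fdiss(c(2, 12, 24), weibull_params(pars[1], pars[2])))
    fit <- fit_weibull(pts)
    expect_equal(fit$params$alpha, pars[1], tolerance = 1e-6)
    expect_equal(fit$params$beta, pars[2], tolerance = 1e-6)
  }
})

test_that("degenerate and insufficient dissolution data are flagged", {
  flat <- tibble::tibble(time_h = c(2, 12, 24), dissolved_pct = 0)
  fit <- fit_weibull(flat)
  expect_false(fit$converged)
  expect_true(fit$degenerate)
  expect_error(fit_weibull(tibble::tibble(time_h = 2, dissolved_pct = 10)),
               class = "ropipbpk_insufficient_data")
})

test_that("parameters are recovered from noisy 3-point profiles in the median", {
  truth <- weibull_params(22.24, 1.19)  # 12 mg study arm
  alphas <- betas <- numeric(100)
  for (s in 1:100) {
    pts <- gen_dissolution_points(truth, c(2, 12, 24), cv = 0.02, seed = s)
    fit <- fit_weibull(pts)
    alphas[s] <- fit$params$alpha
    betas[s] <- fit$params$beta
  }
  expect_lt(abs(median(alphas) - truth$alpha) / truth$alpha, 0.10)
  expect_lt(abs(median(betas) - truth$beta) / truth$beta, 0.10)
})

test_that("dissolution CSV and fitted-parameter JSON round-trip", {
  pts <- gen_dissolution_points(ref_weibull(), c(2, 12, 24), cv = 0, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(pts, csv, row.names = FALSE)
  rt <- read_dissolution_csv(csv)
  expect_equal(rt$dissolved_pct, pts$dissolved_pct)
  fit <- fit_weibull(rt)
  js <- withr::local_tempfile(fileext = ".json")
  write_weibull_json(fit, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$alpha, fit$params$alpha, tolerance = 1e-9)
  expect_true(parsed$converged)
})

test_that("weibull_fit tidiers expose estimates and fit quality", {
  pts <- gen_dissolution_points(ref_weibull(), c(2, 12, 24), cv = 0, seed = 1)
  fit <- fit_weibull(pts)
  td <- tidy(fit)
  expect_setequal(td$term, c("alpha", "beta", "fmax", "lag"))
  expect_equal(glance(fit)$nobs, 3L)
  expect_s3_class(autoplot(fit), "ggplot")
})
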
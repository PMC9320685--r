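test_that("noise-free dissolution points lie exactly on the generating curve", {
  truth <- ref_weibull()
  pts <- gen_dissolution_points(truth, c(2, 12, 24), cv = 0, seed = 1)
  expect_equal(pts$dissolved_pct, 100 * weibull_fdiss(c(2, 12, 24), truth))
  expect_equal(pts$dissolved_pct, c(7.19, 55.45, 86.90), tolerance = 1e-3)
  # round trip through the fitter recovers the truth
  fit <- fit_weibull(pts)
  expect_equal(fit$params$alpha, truth$alpha, tolerance = 1e-6)
  expect_equal(fit$params$beta, truth$beta, tolerance = 1e-6)
})

test_that("dissolution generator is seed-reproducible and clipped to the assay range", {
  a <- gen_dissolution_points(ref_weibull(), c(2, 12, 24), cv = 0.1, seed = 8)
  b <- gen_dissolution_points(ref_weibull(), c(2, 12, 24), cv = 0.1, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, gen_dissolution_points(ref_weibull(), c(2, 12, 24),
                                                   cv = 0.1, seed = 9)))
  big <- gen_dissolution_points(weibull_params(1, 2), c(5, 10, 20), cv = 0.5, seed = 1)
  expect_true(all(big$dissolved_pct <= 105))
  expect_error(gen_dissolution_points(ref_weibull(), c(3, 2), cv = 0))
})

test_that("noise-free pseudo-observations verify the generating simulation exactly", {
  tt <- seq(0, 24, by = 0.25)
  true_prof <- tibble::tibble(time_h = tt,
                              conc = 50 * (exp(-0.1 * tt) - exp(-0.5 * tt)))
  obs <- gen_observed_pk(true_prof, cv = 0, seed = 1)
  sim_m <- nca_metrics(true_prof, dosing_interval = 24)
  sim_summary <- tibble::tibble(
    metric = c("cmax", "tmax", "auc_0_tau"),
    mean = c(sim_m$cmax, sim_m$tmax, sim_m$auc_0_tau),
    geomean = mean, median = mean)
  fr <- suppressWarnings(fold_assessment(sim_summary, obs$observed))
  expect_equal(fr$fold, rep(1, nrow(fr)))
  expect_true(all(fr$pass))
  # a three-fold shifted observation fails the criterion
  obs3 <- obs$observed; obs3$value <- obs3$value * 3
  fr3 <- suppressWarnings(fold_assessment(sim_summary, obs3))
  expect_equal(fr3$fold, rep(3, nrow(fr3)), tolerance = 1e-12)
  expect_false(any(fr3$pass))
})

test_that("pure residual noise rarely breaches the two-fold criterion", {
  tt <- seq(0, 24, by = 0.5)
  true_prof <- tibble::tibble(time_h = tt,
                              conc = 50 * (exp(-0.1 * tt) - exp(-0.5 * tt)))
  truth_m <- nca_metrics(true_prof, dosing_interval = 24)
  folds <- purrr::map(1:200, function(s) {
    noisy <- gen_observed_pk(true_prof, cv = 0.2, seed = s)
    m <- noisy$observed
    c(cmax = max(m$value[m$metric == "cmax"] / truth_m$cmax,
                 truth_m$cmax / m$value[m$metric == "cmax"]),
      auc = max(m$value[m$metric == "auc_0_tau"] / truth_m$auc_0_tau,
                truth_m$auc_0_tau / m$value[m$metric == "auc_0_tau"]))
  }) |> purrr::list_c()
  expect_gte(mean(folds <= 2), 0.95)
})

test_that("incubation datasets round-trip through the fu_inc fitter", {
  dat <- gen_incubation_data(0.39, k_int = 2, timepoints = seq(0, 2, 0.2), cv = 0)
  expect_lt(abs(fit_fu_inc(dat, k_int = 2)$estimate - 0.39), 1e-3)
  expect_identical(gen_incubation_data(0.5, seed = 3),
                   gen_incubation_data(0.5, seed = 3))
  # truth at the upper bound never yields an estimate above it
  at_bound <- gen_incubation_data(1, k_int = 2, cv = 0.05, seed = 4)
  expect_lte(fit_fu_inc(at_bound, k_int = 2)$estimate, 1)
})
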
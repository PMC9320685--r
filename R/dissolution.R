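#' Weibull release parameters
#'
#' Constructs the parameter set of the empirical Weibull cumulative release
#' function used for the prolonged-release tablet,
#' \deqn{F_{diss}(t) = F_{max}\,\bigl(1 - e^{-(t-lag)^\beta/\alpha}\bigr),}
#' the form in which quality-control dissolution profiles are carried through
#' the absorption model. Note the exponent is \eqn{-(t-lag)^\beta/\alpha}
#' (not \eqn{-((t-lag)/\alpha)^\beta}), so `alpha` carries units of
#' h^`beta`; many texts use the other convention and the two are not
#' interchangeable. The magnitudes of fitted `alpha` values (tens of
#' h^`beta` for a 24-h product) only make sense under this form.
#'
#' @param alpha Time-scale parameter (h^beta), > 0.
#' @param beta Shape exponent (dimensionless), > 0.
#' @param fmax Asymptotic fraction of dose released, in (0, 1].
#' @param lag Lag time before any release (h), >= 0.
#'
#' @return An object of class `weibull_params`.
#' @examples
#' weibull_params(33.70, 1.33)
#' @export
weibull_params <- function(alpha, beta, fmax = 1, lag = 0) {
  vals <- c(alpha = alpha, beta = beta, fmax = fmax, lag = lag)
  if (!all(is.finite(vals))) {
    abort("All Weibull parameters must be finite.", class = "ropipbpk_invalid_parameter")
  }
  if (alpha <= 0 || beta <= 0) {
    abort("`alpha` and `beta` must be positive.", class = "ropipbpk_invalid_parameter")
  }
  if (fmax <= 0 || fmax > 1) {
    abort("`fmax` must be in (0, 1].", class = "ropipbpk_invalid_parameter")
  }
  if (lag < 0) {
    abort("`lag` must be non-negative.", class = "ropipbpk_invalid_parameter")
  }
  structure(list(alpha = alpha, beta = beta, fmax = fmax, lag = lag),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("<weibull_params> alpha = %.4g h^beta, beta = %.4g, fmax = %.3g, lag = %.3g h\n",
              x$alpha, x$beta, x$fmax, x$lag))
  invisible(x)
}

as_weibull_params <- function(x) {
  if (inherits(x, "weibull_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(weibull_params(x$alpha, x$beta, x$fmax %||% 1, x$lag %||% 0))
  }
  abort("Cannot interpret input as Weibull parameters.")
}

#' Cumulative fraction dissolved
#'
#' Evaluates the Weibull cumulative release curve at times `t`. Returns 0 at
#' and before the lag time; the curve is monotone non-decreasing and bounded
#' by `fmax`.
#'
#' @param t Time(s) since dosing (h), >= 0. Vectorized.
#' @param params A [weibull_params()] object (or coercible list).
#'
#' @return Numeric vector of fractions of dose dissolved, in \[0, fmax\].
#' @examples
#' weibull_fdiss(c(2, 12, 24), weibull_params(33.70, 1.33))
#' @export
weibull_fdiss <- function(t, params) {
  params <- as_weibull_params(params)
  if (!all(is.finite(t)) || any(t < 0)) {
    abort("`t` must be finite and non-negative.", class = "ropipbpk_invalid_parameter")
  }
  dt <- pmax(t - params$lag, 0)
  params$fmax * (1 - exp(-dt^params$beta / params$alpha))
}

#' Formulation release rate
#'
#' Analytic time-derivative of `dose * weibull_fdiss(t)`, the mass release
#' rate (mg/h) the gut model consumes as its dissolution input. For
#' `beta < 1` the derivative is singular at `t = lag`; the rate is then
#' capped at its value a small offset (`eps`, default 1e-6 h) past the lag so
#' the integrator always sees a finite right-hand side. The cap affects the
#' integral of the rate by less than `eps` worth of release.
#'
#' @inheritParams weibull_fdiss
#' @param dose Dose in the formulation (mg), > 0.
#' @param eps Offset (h) used to cap the singular rate when `beta < 1`.
#'
#' @return Release rate(s) in mg/h.
#' @examples
#' weibull_release_rate(0, weibull_params(10, 1), dose = 1)  # dose/alpha
#' @export
weibull_release_rate <- function(t, params, dose, eps = 1e-6) {
  params <- as_weibull_params(params)
  if (!all(is.finite(t)) || any(t < 0)) {
    abort("`t` must be finite and non-negative.", class = "ropipbpk_invalid_parameter")
  }
  if (!is.finite(dose) || dose <= 0) {
    abort("`dose` must be positive.", class = "ropipbpk_invalid_parameter")
  }
  dt <- t - params$lag
  out <- numeric(length(t))
  live <- dt > 0
  if (params$beta < 1) {
    dtl <- pmax(dt[live], eps)
  } else {
    dtl <- dt[live]
  }
  out[live] <- dose * params$fmax * exp(-dtl^params$beta / params$alpha) *
    params$beta * dtl^(params$beta - 1) / params$alpha
  # t exactly at lag with beta <= 1: use the capped/limit value
  at_lag <- dt == 0
  if (any(at_lag)) {
    if (params$beta == 1) {
      out[at_lag] <- dose * params$fmax / params$alpha
    } else if (params$beta < 1) {
      out[at_lag] <- dose * params$fmax * exp(-eps^params$beta / params$alpha) *
        params$beta * eps^(params$beta - 1) / params$alpha
    }
  }
  out
}

#' Fit Weibull release parameters to dissolution points
#'
#' Least-squares fit of the Weibull release curve to sparse dissolution data
#' (typically the three timepoints reported in a certificate of analysis).
#' `fmax` and `lag` are held fixed (the quality-control convention for this
#' product: complete release, no lag); `alpha` and `beta` are estimated by
#' unweighted least squares in log-parameter space, which enforces
#' positivity without explicit constraints. Three starting points are used
#' to guard against the identifiability cliff of 3-point profiles, and the
#' best converged solution is kept.
#'
#' @param data A data frame with columns `time_h` and `dissolved_pct`
#'   (percent of dose, 0--105).
#' @param fmax,lag Fixed asymptote (fraction) and lag (h).
#'
#' @return An object of class `weibull_fit`: the fitted [weibull_params()],
#'   residual sum of squares (on the fraction scale), a convergence flag and
#'   the data. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' pts <- tibble::tibble(time_h = c(2, 12, 24),
#'                       dissolved_pct = 100 * weibull_fdiss(c(2, 12, 24),
#'                                                           weibull_params(33.7, 1.33)))
#' fit_weibull(pts)
#' @export
fit_weibull <- function(data, fmax = 1, lag = 0) {
  stopifnot(is.data.frame(data))
  if (!all(c("time_h", "dissolved_pct") %in% names(data))) {
    abort("`data` must have columns `time_h` and `dissolved_pct`.")
  }
  data <- dplyr::arrange(dplyr::as_tibble(data), .data$time_h)
  validate_dissolution_points(data)
  t_obs <- data$time_h
  y_obs <- data$dissolved_pct / 100  # percent at the boundary, fraction inside
  if (length(unique(t_obs)) < 2) {
    abort("At least two points with distinct times are required.",
          class = "ropipbpk_insufficient_data")
  }
  degenerate <- all(y_obs <= 0)

  resid_fn <- function(logpar) {
    p <- weibull_params(exp(logpar[1]), exp(logpar[2]), fmax = fmax, lag = lag)
    weibull_fdiss(t_obs, p) - y_obs
  }
  # starts bracket slow/nominal/fast release for a 24-h-scale product
  starts <- list(c(log(10), log(1)), c(log(30), log(1.3)), c(log(100), log(0.9)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    if (is.null(best) || rss < best$rss - 1e-14) {
      best <- list(fit = fit, rss = rss, converged = conv)
    }
  }
  if (is.null(best)) {
    abort("Weibull fit failed from all starting points.", class = "ropipbpk_fit_failure")
  }
  params <- weibull_params(exp(best$fit$par[1]), exp(best$fit$par[2]),
                           fmax = fmax, lag = lag)
  converged <- best$converged && !degenerate
  structure(
    list(params = params, rss = best$rss, converged = converged,
         degenerate = degenerate, data = data,
         n_points = nrow(data), optimizer_info = best$fit$info),
    class = "weibull_fit")
}

validate_dissolution_points <- function(data) {
  if (any(!is.finite(data$time_h)) || any(data$time_h < 0)) {
    abort("Dissolution times must be finite and non-negative.")
  }
  if (any(diff(data$time_h) < 0)) {
    abort("Dissolution times must be increasing.")
  }
  if (any(!is.finite(data$dissolved_pct)) ||
      any(data$dissolved_pct < 0) || any(data$dissolved_pct > 105)) {
    abort("`dissolved_pct` must lie in [0, 105] (allows assay noise above 100).")
  }
  invisible(data)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> %d points; alpha = %.4g, beta = %.4g (fmax = %.3g, lag = %.3g)\n",
              x$n_points, x$params$alpha, x$params$beta, x$params$fmax, x$params$lag))
  cat(sprintf("  RSS = %.3g (fraction scale); converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' @rdname fit_weibull
#' @param x A `weibull_fit` object.
#' @param ... Unused.
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble(term = c("alpha", "beta", "fmax", "lag"),
         estimate = c(x$params$alpha, x$params$beta, x$params$fmax, x$params$lag),
         fixed = c(FALSE, FALSE, TRUE, TRUE))
}

#' @rdname fit_weibull
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, degenerate = x$degenerate,
         nobs = x$n_points)
}

#' Read a dissolution profile CSV
#'
#' Reads the package's dissolution exchange format: a header
#' `time_h,dissolved_pct` and one profile per file. Percent-of-dose values
#' are kept as percent at this boundary; model-facing code works in
#' fractions.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `time_h`, `dissolved_pct`.
#' @export
read_dissolution_csv <- function(path) {
  df <- as_tibble(read.csv(path))
  if (!all(c("time_h", "dissolved_pct") %in% names(df))) {
    abort(sprintf("'%s' must have header time_h,dissolved_pct", path))
  }
  validate_dissolution_points(df)
  df
}

#' Write fitted Weibull parameters as JSON
#'
#' @param fit A `weibull_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weibull_json <- function(fit, path) {
  stopifnot(inherits(fit, "weibull_fit"))
  jsonlite::write_json(
    list(alpha = fit$params$alpha, beta = fit$params$beta,
         fmax = fit$params$fmax, lag = fit$params$lag,
         rss = fit$rss, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_weibull
#' @param object A `weibull_fit` object.
#' @export
autoplot.weibull_fit <- function(object, ...) {
  tt <- seq(0, max(object$data$time_h) * 1.1, length.out = 200)
  curve <- tibble(time_h = tt,
                  dissolved_pct = 100 * weibull_fdiss(tt, object$params))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h, y = .data$dissolved_pct)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Time (h)", y = "Dissolved (% of dose)",
                  title = sprintf("Weibull fit: alpha = %.3g, beta = %.3g",
                                  object$params$alpha, object$params$beta)) +
    ggplot2::theme_minimal()
}
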
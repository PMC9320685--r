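#' Noncompartmental PK metrics
#'
#' Computes Cmax, Tmax, AUC over the dosing interval, the terminal slope
#' lambda-z and AUC to infinity from a concentration--time profile.
#' Cmax/Tmax are the discrete maximum (earliest time on ties). AUC uses the
#' linear-up/log-down trapezoid by default (`auc_method = "linear"` gives
#' the plain trapezoid). Lambda-z comes from a log-linear regression over
#' the terminal points: every window of the last 3--6 positive
#' concentrations strictly after Tmax is fitted and the best
#' adjusted-R-squared window with a negative slope wins. AUC0-inf adds
#' Clast/lambda-z to the AUC over all sampled points; when lambda-z is not
#' estimable, AUC0-inf is returned as `NA` and flagged while AUC over the
#' interval is still reported.
#'
#' @param profile Data frame with strictly increasing `time_h` and
#'   non-negative `conc` (>= 3 points).
#' @param dosing_interval Interval tau (h) for AUC0-tau; default 24.
#' @param auc_method `"lin_up_log_down"` (default) or `"linear"`.
#'
#' @return A one-row tibble: `cmax`, `tmax`, `auc_0_tau`, `auc_0_inf`,
#'   `lambda_z`, `lambda_z_estimable`, `n_lambda_z`.
#' @examples
#' tt <- seq(0, 48, 0.25)
#' nca_metrics(tibble::tibble(time_h = tt, conc = 10 * exp(-0.1 * tt)))
#' @export
nca_metrics <- function(profile, dosing_interval = 24,
                        auc_method = c("lin_up_log_down", "linear")) {
  auc_method <- match.arg(auc_method)
  stopifnot(is.data.frame(profile), all(c("time_h", "conc") %in% names(profile)))
  if (nrow(profile) < 3) abort("Need at least 3 profile points.",
                               class = "ropipbpk_insufficient_data")
  t <- profile$time_h; y <- profile$conc
  if (any(diff(t) <= 0)) abort("`time_h` must be strictly increasing.")
  if (any(y < 0)) abort("`conc` must be non-negative.")

  if (all(y == 0)) {
    return(tibble(cmax = 0, tmax = t[1], auc_0_tau = 0, auc_0_inf = 0,
                  lambda_z = NA_real_, lambda_z_estimable = FALSE,
                  n_lambda_z = 0L))
  }
  cmax <- max(y)
  tmax <- t[which(y == cmax)[1]]

  auc_0_tau <- trapz_auc(t, y, upper = dosing_interval, method = auc_method)
  lz <- estimate_lambda_z(t, y, tmax)
  auc_all <- trapz_auc(t, y, upper = max(t), method = auc_method)
  clast <- y[max(which(y > 0))]
  auc_0_inf <- if (lz$estimable) auc_all + clast / lz$lambda_z else NA_real_
  tibble(cmax = cmax, tmax = tmax, auc_0_tau = auc_0_tau,
         auc_0_inf = auc_0_inf, lambda_z = lz$lambda_z,
         lambda_z_estimable = lz$estimable, n_lambda_z = lz$n)
}

# Trapezoidal AUC on [0, upper]; interpolates the profile at `upper` if it
# falls between samples. Log-down segments use the log trapezoid when both
# endpoints are positive and declining.
trapz_auc <- function(t, y, upper, method) {
  keep <- t <= upper + 1e-12
  t2 <- t[keep]; y2 <- y[keep]
  if (max(t2) < upper && max(t) > upper) {
    i <- findInterval(upper, t)
    yi <- y[i] + (y[i + 1] - y[i]) * (upper - t[i]) / (t[i + 1] - t[i])
    t2 <- c(t2, upper); y2 <- c(y2, yi)
  }
  dt <- diff(t2); y1 <- y2[-length(y2)]; yb <- y2[-1]
  lin <- dt * (y1 + yb) / 2
  if (method == "linear") return(sum(lin))
  logdown <- yb < y1 & yb > 0 & y1 > 0
  seg <- lin
  seg[logdown] <- dt[logdown] * (y1[logdown] - yb[logdown]) /
    log(y1[logdown] / yb[logdown])
  sum(seg)
}

estimate_lambda_z <- function(t, y, tmax) {
  ok <- which(t > tmax & y > 0)
  best <- list(lambda_z = NA_real_, estimable = FALSE, n = 0L, adj_r2 = -Inf)
  if (length(ok) < 3) return(best)
  for (k in 3:min(6, length(ok))) {
    idx <- tail(ok, k)
    fit <- lm(log(y[idx]) ~ t[idx])
    slope <- coef(fit)[2]
    if (!is.finite(slope) || slope >= 0) next
    # noiseless profiles fit exactly; the "perfect fit" warning is expected
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (ar2 > best$adj_r2) {
      best <- list(lambda_z = -unname(slope), estimable = TRUE,
                   n = as.integer(k), adj_r2 = ar2)
    }
  }
  best
}
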
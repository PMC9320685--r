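#' Default permeability correlation coefficients
#'
#' Two chained log--log linear correlations convert an apparent PAMPA
#' permeability to a human effective jejunal permeability (Peff):
#' PAMPA -> Caco-2, then Caco-2 -> Peff. The Caco-2 -> Peff step uses the
#' widely used literature regression
#' `log10(Peff, 1e-4 cm/s) = 0.4926 * log10(Papp_Caco2, 1e-6 cm/s) - 0.1454`.
#' The PAMPA -> Caco-2 step has unit slope and an intercept of 0.28774
#' calibrated so the full chain maps a PAMPA value of 26.8e-6 cm/s onto the
#' reference jejunal permeability of 5.01e-4 cm/s used for ropinirole; both
#' steps are overridable.
#'
#' @return A list with elements `pampa_caco2` and `caco2_peff`, each
#'   `list(slope, intercept)` on the log10 scale.
#' @export
default_permeability_config <- function() {
  list(
    pampa_caco2 = list(slope = 1.0, intercept = 0.2877355),
    caco2_peff  = list(slope = 0.4926, intercept = -0.1454)
  )
}

loglog_apply <- function(x, corr, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("%s input permeability must be positive and finite.", what),
          class = "ropipbpk_domain_error")
  }
  if (corr$slope <= 0) abort("Correlation slope must be positive.")
  10^(corr$slope * log10(x) + corr$intercept)
}

#' Permeability scaling chain
#'
#' `pampa_to_caco2()` maps a PAMPA apparent permeability (1e-6 cm/s) to a
#' Caco-2 apparent permeability (1e-6 cm/s); `caco2_to_peff()` maps Caco-2
#' (1e-6 cm/s) to human effective jejunal permeability (1e-4 cm/s);
#' `predict_peff()` chains the two. Each step is a log--log linear
#' correlation, monotone increasing in its input.
#'
#' @param papp_pampa,papp_caco2 Input permeabilities (1e-6 cm/s), > 0.
#' @param config Correlation coefficients, see
#'   [default_permeability_config()].
#'
#' @return Numeric permeability on the output scale.
#' @examples
#' predict_peff(26.8)  # ~5.01 (1e-4 cm/s)
#' @export
pampa_to_caco2 <- function(papp_pampa, config = default_permeability_config()) {
  loglog_apply(papp_pampa, config$pampa_caco2, "PAMPA")
}

#' @rdname pampa_to_caco2
#' @export
caco2_to_peff <- function(papp_caco2, config = default_permeability_config()) {
  loglog_apply(papp_caco2, config$caco2_peff, "Caco-2")
}

#' @rdname pampa_to_caco2
#' @export
predict_peff <- function(papp_pampa, config = default_permeability_config()) {
  caco2_to_peff(pampa_to_caco2(papp_pampa, config), config)
}

#' Segmental absorption rate constants
#'
#' Converts an effective permeability into first-order absorption rate
#' constants per gut segment using cylindrical surface-to-volume scaling,
#' `ka = 2 * Peff / radius`, unit-converted to 1/h, and multiplied by each
#' segment's relative-absorption scalar (0 for the stomach by default).
#'
#' @param peff Effective permeability (1e-4 cm/s), >= 0.
#' @param geometry A gut geometry tibble, see [gut_geometry()].
#'
#' @return The geometry tibble with an added `ka` column (1/h).
#' @examples
#' segmental_ka(5.01, gut_geometry())
#' @export
segmental_ka <- function(peff, geometry = gut_geometry()) {
  if (!is.finite(peff) || peff < 0) abort("`peff` must be non-negative and finite.")
  if (any(geometry$radius_cm <= 0)) abort("Segment radii must be positive.")
  dplyr::mutate(geometry,
                ka = 2 * peff * 1e-4 / .data$radius_cm * 3600 * .data$rel_abs)
}
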
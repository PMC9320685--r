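#' Drug property set
#'
#' Physicochemistry, blood binding, permeability and in-vitro metabolism
#' inputs for the PBPK model. All fields are on the scales used throughout
#' the package: permeabilities in the customary 1e-6 (PAMPA/Caco-2) and
#' 1e-4 (Peff) cm/s units, enzyme kinetics in nmol/h/mg microsomal protein
#' and umol/L.
#'
#' @param mw Molecular weight (g/mol).
#' @param logp Neutral-species octanol:buffer partition coefficient (log10).
#' @param compound_type `"monoprotic_base"` or `"neutral"`.
#' @param pka Dissociation constant (for bases).
#' @param bp Blood-to-plasma concentration ratio.
#' @param fu Fraction unbound in plasma, (0, 1].
#' @param fu_mic Fraction unbound in the microsomal incubation, (0, 1].
#' @param papp_pampa Apparent PAMPA permeability (1e-6 cm/s).
#' @param pathways Enzyme kinetics tibble with columns `enzyme`, `pathway`,
#'   `vmax` (nmol/h/mg), `km` (umol/L). `km` is interpreted as a
#'   concentration in umol/L.
#'
#' @return An object of class `drug_properties`.
#' @seealso [drug_ropinirole()]
#' @export
drug_properties <- function(mw, logp, compound_type = c("monoprotic_base", "neutral"),
                            pka = NA_real_, bp, fu, fu_mic = NA_real_,
                            papp_pampa = NA_real_, pathways = NULL) {
  compound_type <- match.arg(compound_type)
  if (fu <= 0 || fu > 1) abort("`fu` must be in (0, 1].")
  if (!is.na(fu_mic) && (fu_mic <= 0 || fu_mic > 1)) abort("`fu_mic` must be in (0, 1].")
  if (bp <= 0) abort("`bp` must be positive.")
  if (compound_type == "monoprotic_base" && !is.finite(pka)) {
    abort("A monoprotic base needs a finite `pka`.")
  }
  if (!is.null(pathways)) {
    stopifnot(all(c("enzyme", "pathway", "vmax", "km") %in% names(pathways)))
    if (any(pathways$vmax <= 0) || any(pathways$km <= 0)) {
      abort("Enzyme `vmax` and `km` must be positive.")
    }
    pathways <- as_tibble(pathways)
  }
  structure(list(mw = mw, logp = logp, compound_type = compound_type, pka = pka,
                 bp = bp, fu = fu, fu_mic = fu_mic, papp_pampa = papp_pampa,
                 pathways = pathways),
            class = "drug_properties")
}

#' @export
print.drug_properties <- function(x, ...) {
  cat(sprintf("<drug_properties> MW %.5g, logP %.3g, %s (pKa %.4g), B/P %.3g, fu %.3g\n",
              x$mw, x$logp, x$compound_type, x$pka, x$bp, x$fu))
  if (!is.null(x$pathways)) {
    cat(sprintf("  %d enzyme pathway(s); fu_mic %.3g\n", nrow(x$pathways), x$fu_mic))
  }
  invisible(x)
}

#' Ropinirole enzyme kinetics
#'
#' The four recombinant-enzyme pathways driving hepatic elimination:
#' N-despropylation and 7-hydroxylation, each by CYP1A2 and CYP3A4.
#' Vmax in nmol/h/mg microsomal protein, Km in umol/L.
#'
#' @return A tibble with columns `enzyme`, `pathway`, `vmax`, `km`.
#' @export
enzyme_pathways_ropinirole <- function() {
  tribble(
    ~enzyme,   ~pathway,          ~vmax,  ~km,
    "CYP1A2",  "N-despropylation",  7.83,   34.63,
    "CYP3A4",  "N-despropylation", 523.33, 2700.00,
    "CYP1A2",  "hydroxylation",     6.93,   45.87,
    "CYP3A4",  "hydroxylation",    255.33, 3933.33
  )
}

#' Ropinirole drug properties
#'
#' The reference parameter set for ropinirole: a freely soluble, highly
#' permeable (BCS class I) monoprotic base eliminated almost entirely by
#' hepatic CYP1A2/CYP3A4 metabolism.
#'
#' @return A [drug_properties()] object.
#' @examples
#' drug_ropinirole()
#' @export
drug_ropinirole <- function() {
  drug_properties(
    mw = 260.38, logp = 2.7, compound_type = "monoprotic_base", pka = 9.79,
    bp = 1.09, fu = 0.68, fu_mic = 0.39, papp_pampa = 26.8,
    pathways = enzyme_pathways_ropinirole())
}

#' Load drug properties from a YAML file
#'
#' Reads a drug file mirroring the package's reference `ropinirole.yaml`
#' (shipped under `inst/extdata/`).
#'
#' @param path Path to a YAML drug file.
#' @return A [drug_properties()] object.
#' @export
load_drug <- function(path) {
  if (!file.exists(path)) abort(sprintf("Drug file '%s' does not exist.", path))
  y <- yaml::read_yaml(path)
  required <- c("mw", "logp", "compound_type", "bp", "fu")
  missing <- setdiff(required, names(y))
  if (length(missing)) {
    abort(sprintf("Drug file is missing field(s): %s", paste(missing, collapse = ", ")))
  }
  pw <- NULL
  if (!is.null(y$pathways)) {
    pw <- purrr::map(y$pathways, as_tibble) |> purrr::list_rbind()
  }
  drug_properties(mw = y$mw, logp = y$logp, compound_type = y$compound_type,
                  pka = y$pka %||% NA_real_, bp = y$bp, fu = y$fu,
                  fu_mic = y$fu_mic %||% NA_real_,
                  papp_pampa = y$papp_pampa %||% NA_real_, pathways = pw)
}
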
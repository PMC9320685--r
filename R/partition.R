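#' Tissue composition table for partition-coefficient prediction
#'
#' Fractional tissue volumes of extracellular and intracellular water,
#' neutral lipids and neutral phospholipids, and acidic phospholipid
#' concentrations (mg/g tissue), for the organs of the full PBPK model,
#' plus blood cells. Values are the published composition data underlying
#' the Rodgers--Rowland tissue-partitioning equations, as commonly
#' tabulated in the open PBPK literature; residual differences from any
#' simulator-internal copy are absorbed by the wide tolerance placed on
#' distribution-volume predictions.
#'
#' @return A tibble with columns `tissue`, `f_ew`, `f_iw`, `f_nl`, `f_np`,
#'   `ap_mg_g`.
#' @export
tissue_composition <- function() {
  tribble(
    ~tissue,      ~f_ew, ~f_iw, ~f_nl,  ~f_np,  ~ap_mg_g,
    "adipose",    0.135, 0.017, 0.7900, 0.0020, 0.40,
    "bone",       0.100, 0.346, 0.0740, 0.0011, 0.67,
    "brain",      0.162, 0.620, 0.0510, 0.0565, 0.40,
    "gut",        0.282, 0.475, 0.0487, 0.0163, 2.41,
    "heart",      0.320, 0.456, 0.0115, 0.0166, 2.25,
    "kidney",     0.273, 0.483, 0.0207, 0.0162, 5.03,
    "liver",      0.161, 0.573, 0.0348, 0.0252, 4.56,
    "lung",       0.336, 0.446, 0.0220, 0.0128, 3.91,
    "muscle",     0.118, 0.630, 0.0238, 0.0072, 1.53,
    "skin",       0.382, 0.291, 0.0284, 0.0111, 1.32,
    "spleen",     0.207, 0.579, 0.0201, 0.0198, 3.18,
    "blood_cell", 0.000, 0.603, 0.0017, 0.0029, 0.50
  )
}

#' Reference organ volumes and blood flows
#'
#' Organ volumes (L) and blood flows (L/h) for a 70-kg reference adult.
#' Flows sum to the cardiac output; hepatic inflow is the hepatic artery
#' plus the portal drainage of gut and spleen (total 90 L/h). The
#' population module rescales these with body weight and age.
#'
#' @return A tibble with columns `organ`, `volume_L`, `flow_Lh`. Blood-side
#'   rows (`arterial`, `venous`) carry volumes only; `lung` receives the
#'   full cardiac output in series.
#' @export
organ_reference <- function() {
  tribble(
    ~organ,     ~volume_L, ~flow_Lh,
    "adipose",   15.00,     18.5,
    "bone",       6.00,     19.5,
    "brain",      1.45,     46.0,
    "gut",        1.20,     45.0,
    "heart",      0.33,     15.0,
    "kidney",     0.31,     74.0,
    "liver",      1.65,     37.0,   # hepatic artery; portal adds gut + spleen
    "lung",       0.53,     NA,     # in series, carries cardiac output
    "muscle",    29.00,     66.0,
    "skin",       2.60,     20.0,
    "spleen",     0.19,      8.0,
    "arterial",   1.70,     NA,
    "venous",     3.70,     NA
  )
}

#' Rodgers--Rowland tissue-to-plasma partition coefficients
#'
#' Predicts unbound tissue-to-plasma partition coefficients (Kpu) with the
#' Rodgers--Rowland mechanistic equations. For a moderate-to-strong
#' monoprotic base (pKa > pH) partitioning comprises tissue water
#' (ionization-corrected at intracellular pH 7.0 vs plasma pH 7.4),
#' electrostatic association of the ionized species with acidic
#' phospholipids (association constant `KaAP` calibrated from the
#' blood-cell partition implied by the blood-to-plasma ratio), and
#' partitioning of the neutral species into neutral lipids and neutral
#' phospholipids. For a neutral compound the ionization and
#' acidic-phospholipid terms vanish and Kpu reduces to water plus neutral
#' lipid partitioning.
#'
#' @param drug A [drug_properties()] object.
#' @param tissues Composition table, see [tissue_composition()].
#' @param hematocrit Hematocrit used to back out the blood-cell partition.
#' @param ph_plasma,ph_iw,ph_bc Plasma, intracellular-water and blood-cell
#'   pH.
#'
#' @return A tibble `tissue`, `kpu`, `kp` (`kp = kpu * fu`), with the
#'   blood-cell Kpu and `KaAP` as attributes `kpu_bc`, `ka_ap`.
#' @examples
#' kpu_rodgers_rowland(drug_ropinirole())
#' @export
kpu_rodgers_rowland <- function(drug, tissues = tissue_composition(),
                                hematocrit = 0.45, ph_plasma = 7.4,
                                ph_iw = 7.0, ph_bc = 7.22) {
  stopifnot(inherits(drug, "drug_properties"))
  p_ow <- 10^drug$logp
  nl_term <- function(f_nl, f_np) p_ow * f_nl + (0.3 * p_ow + 0.7) * f_np

  tc <- tissues |> filter(.data$tissue != "blood_cell")
  bc <- tissues |> filter(.data$tissue == "blood_cell")
  if (nrow(bc) != 1) abort("Composition table needs a `blood_cell` row.",
                           class = "ropipbpk_configuration_error")

  if (drug$compound_type == "monoprotic_base" && drug$pka > ph_plasma) {
    ion_p  <- 1 + 10^(drug$pka - ph_plasma)
    ion_iw <- 1 + 10^(drug$pka - ph_iw)
    ion_bc <- 1 + 10^(drug$pka - ph_bc)
    kpu_bc <- (drug$bp - (1 - hematocrit)) / (hematocrit * drug$fu)
    if (kpu_bc <= 0) abort("Implied blood-cell partition is non-positive; check B/P, fu, hematocrit.")
    ka_ap <- (kpu_bc - ion_bc / ion_p * bc$f_iw - nl_term(bc$f_nl, bc$f_np) / ion_p) *
      ion_p / (bc$ap_mg_g * 10^(drug$pka - ph_bc))
    kpu <- tc$f_ew + ion_iw / ion_p * tc$f_iw +
      ka_ap * tc$ap_mg_g * 10^(drug$pka - ph_iw) / ion_p +
      nl_term(tc$f_nl, tc$f_np) / ion_p
  } else {
    # neutral-species limit: water plus neutral-lipid partitioning only
    kpu_bc <- bc$f_iw + nl_term(bc$f_nl, bc$f_np)
    ka_ap <- 0
    kpu <- tc$f_ew + tc$f_iw + nl_term(tc$f_nl, tc$f_np)
  }
  if (any(kpu <= 0)) abort("Non-positive Kpu predicted; inputs are inconsistent.")
  out <- tibble(tissue = tc$tissue, kpu = kpu, kp = kpu * drug$fu)
  attr(out, "kpu_bc") <- kpu_bc
  attr(out, "ka_ap") <- ka_ap
  out
}

#' Fraction unbound in the enterocyte
#'
#' Predicted with the same partitioning machinery applied to gut tissue:
#' the unbound fraction in the enterocyte is taken as the reciprocal of the
#' gut Kpu, capped at 1.
#'
#' @inheritParams kpu_rodgers_rowland
#' @return A scalar in (0, 1].
#' @export
fu_gut_rodgers_rowland <- function(drug, tissues = tissue_composition()) {
  kpu <- kpu_rodgers_rowland(drug, tissues)
  kpu_gut <- kpu$kpu[kpu$tissue == "gut"]
  if (!length(kpu_gut)) abort("Composition table has no `gut` row.",
                              class = "ropipbpk_configuration_error")
  min(1 / kpu_gut, 1)
}

#' Steady-state volume of distribution
#'
#' Assembles Vss (plasma-referenced, per kg body weight) from the
#' tissue-level partition coefficients:
#' \deqn{V_{ss} = V_p + V_{E}\,Kpu_{BC}\,fu + \sum_t V_t\,Kpu_t\,fu}
#' with plasma volume, the erythrocyte term via the blood-cell partition,
#' and the perfused organs.
#'
#' @param kpu Partition table from [kpu_rodgers_rowland()].
#' @param drug A [drug_properties()] object.
#' @param organs Organ volume table, see [organ_reference()].
#' @param body_weight_kg Body weight used for normalization.
#' @param hematocrit Hematocrit splitting blood volume into plasma and
#'   cells.
#'
#' @return Vss in L/kg.
#' @examples
#' drug <- drug_ropinirole()
#' predict_vss(kpu_rodgers_rowland(drug), drug)
#' @export
predict_vss <- function(kpu, drug, organs = organ_reference(),
                        body_weight_kg = 70, hematocrit = 0.45) {
  stopifnot(inherits(drug, "drug_properties"))
  kpu_bc <- attr(kpu, "kpu_bc")
  if (is.null(kpu_bc)) abort("`kpu` must come from kpu_rodgers_rowland().")
  blood_v <- sum(organs$volume_L[organs$organ %in% c("arterial", "venous")])
  v_plasma <- blood_v * (1 - hematocrit)
  v_rbc <- blood_v * hematocrit
  perf <- organs |>
    filter(!.data$organ %in% c("arterial", "venous")) |>
    inner_join(kpu, by = c(organ = "tissue"))
  if (nrow(perf) == 0) abort("No organs matched the partition table.")
  vss_L <- v_plasma + v_rbc * kpu_bc * drug$fu + sum(perf$volume_L * perf$kpu * drug$fu)
  vss_L / body_weight_kg
}
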
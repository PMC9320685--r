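---
title: "Methods: mechanistic absorption and PBPK trial simulation for prolonged-release ropinirole"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanistic absorption and PBPK trial simulation for prolonged-release ropinirole}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ropipbpk)
```

## Scope and model structure

`ropipbpk` implements a desk-scale, fully open physiologically based
pharmacokinetic (PBPK) workflow for a BCS class I compound, ropinirole,
administered as a 24-hour prolonged-release (Geomatrix-type) tablet. The
pipeline is:

1. **Dissolution**: quality-control dissolution profiles — often just three
   timepoints from a certificate of analysis — are condensed into a Weibull
   cumulative release function.
2. **Gut absorption**: the fitted release rate drives a nine-compartment
   gastrointestinal transit/dissolution/absorption system (stomach, seven
   small-intestine segments, colon).
3. **Systemic disposition**: absorbed drug enters the liver via the portal
   vein and distributes through a full-body perfusion-limited PBPK model
   with Rodgers–Rowland tissue partitioning; elimination is hepatic, scaled
   up from microsomal enzyme kinetics (IVIVE) through the well-stirred
   liver model.
4. **Trial simulation**: virtual subjects are sampled from transparent
   population specifications and carried through multiple-dose titration
   regimens; noncompartmental metrics and population summaries feed a
   two-fold simulated-versus-observed verification.

Because ropinirole is freely soluble and highly permeable, release from the
formulation — not intrinsic dissolution or permeation — is the
rate-limiting step for absorption. That assumption shapes several design
choices below.

## The Weibull release model

The cumulative fraction released is

$$F_{diss}(t) = F_{max}\left(1 - e^{-(t - t_{lag})^{\beta}/\alpha}\right),$$

with $F_{max} = 1$ and $t_{lag} = 0$ for this product. Note the exponent:
$\alpha$ divides $(t-t_{lag})^\beta$ directly, so it carries units of
h$^\beta$ — many texts instead use $((t-t_{lag})/\alpha)^\beta$. The two
conventions are not interchangeable, and fitted $\alpha$ values in the
tens only make sense under the first. The release *rate* consumed by the
gut model is the analytic derivative of $\text{dose} \cdot F_{diss}$; for
$\beta < 1$ the derivative is singular at $t = t_{lag}$ and is capped at
its value $10^{-6}$ h past the lag, a choice that perturbs the integral of
the rate by less than the cap offset itself.

Fitting uses unweighted least squares on $(\log\alpha, \log\beta)$
(positivity by construction) with three starting points spanning slow to
fast release. Three-point profiles sit on an identifiability cliff: if a
shape saturates the sampling grid (all points near 100% dissolved), many
parameter pairs fit equally well, so the fitter reports a convergence flag
and the residual sum of squares rather than pretending precision. For
24-hour-release shapes ($\alpha \approx 17$–$38$ h$^\beta$,
$\beta \approx 1.1$–$1.4$) the standard 2/12/24 h grid identifies both
parameters to machine precision on noiseless data.

## The gut model

Each of the nine compartments tracks formulation-bound ($A_F$), solid
($A_S$), dissolved ($A_D$) and enterocyte ($C_{ent}$) drug. Movement
between lumped segments is first order at the reciprocal of the mean
residence time. Defaults (all overridable in `gut_geometry()`):

| quantity | default | rationale |
|---|---|---|
| gastric residence | 0.4 h fasted / 1.0 h fed | standard compartmental-transit values |
| small-intestinal transit | 3.3 h, split over 7 segments by anatomical length | standard total SI transit |
| colonic residence (fluid/dissolved) | 12 h | conventional lumped colon value |
| segment radii | 2.0 → 1.25 cm (duodenum → ileum), colon 2.5 cm | anatomy; jejunal reference 1.75 cm |
| stomach / colon absorption scalars | 0 / 1 | no gastric absorption; a permeable base absorbs colonically |

Absorption rate constants come from cylindrical surface-to-volume scaling,
$k_a = 2\,P_{eff}/r$, after a two-step log–log correlation chain maps a
PAMPA apparent permeability to Caco-2 and then to human effective jejunal
permeability. The Caco-2 → $P_{eff}$ step uses the familiar literature
regression (slope 0.4926, intercept −0.1454 on the $10^{-6}$ /
$10^{-4}$ cm/s scales); the PAMPA → Caco-2 step has unit slope with an
intercept of 0.28774, calibrated once so the chain maps ropinirole's
26.8×10⁻⁶ cm/s onto the reference effective permeability of
5.01×10⁻⁴ cm/s. Both steps are configuration, not code.

Three deliberate choices:

* **Released drug is dissolved drug.** Because the formulation controls
  release, released mass bypasses the solid pool by default
  (`bypass_solid = TRUE`); a configuration switch routes it through $A_S$
  with a fast intrinsic dissolution constant instead. Simulations of this
  product are insensitive to the switch.
* **The monolith stays in the colon.** A Geomatrix tablet is a single
  non-disintegrating unit whose colonic residence exceeds the 48-h
  simulation window, so by default intact formulation does not transit out
  of the colon (`formulation_exits_colon = FALSE`); dissolved drug always
  exits with the 12-h colonic residence. With a transiting monolith, most
  of a 24-h release window would postdate colonic exit, collapsing the
  predicted fraction absorbed far below the near-complete absorption
  expected for this drug/formulation; with retention the ropinirole
  configuration absorbs ~94% of an 8 mg dose in 48 h (the
  `fraction_absorbed_8mg` quantity of the acceptance summary).
* **Fed state is a gastric delay only.** No mechanistic food-effect
  physiology is attempted; the fed state lengthens gastric residence and
  nothing else.

Degradation, efflux and gut-wall metabolism terms exist in the equations
but are zero in the ropinirole configuration (passive absorption, no
transporter reports, the dominant enzyme absent from the gut wall). Mass
balance — lumen + enterocyte + absorbed + feces (+ degraded + gut
metabolism) against administered dose — is asserted after every simulation
at 0.1% of dose and typically closes to ~10⁻¹³.

## Tissue partitioning and distribution

Unbound tissue-to-plasma partition coefficients use the Rodgers–Rowland
equations for a moderate-to-strong monoprotic base (pKa 9.79 ≫ plasma pH):
ionization-corrected water partitioning (intracellular pH 7.0 vs plasma
7.4), electrostatic association of the cation with acidic phospholipids,
and neutral-lipid/phospholipid partitioning of the neutral species. The
acidic-phospholipid association constant is back-calculated from the
blood-cell partition implied by the blood-to-plasma ratio (1.09),
hematocrit (0.45) and plasma unbound fraction (0.68). The tissue
composition table ships with the package (`tissue_composition()`), entered
from the published composition values; simulator-internal copies of this
table differ slightly between implementations, which is why the
distribution-volume check carries a ±25% band. With the reference inputs
the package predicts $V_{ss}$ = 3.04 L/kg against the reported 3.37 L/kg
(−10%). The same machinery supplies the enterocyte unbound fraction as
$1/Kpu_{gut}$.

## Clearance

All four microsomal pathways (CYP1A2 and CYP3A4, N-despropylation and
hydroxylation) operate far below their Km at therapeutic concentrations
(µg/L plasma against Km of tens to thousands of µmol/L), so the default
IVIVE is linear: $\sum_i V_{max,i}/K_{m,i}$ = 0.636 mL/h/mg microsomal
protein, divided by the microsomal unbound fraction (0.39), times MPPGL
(40 mg/g) and liver mass (1650 g), giving an unbound intrinsic clearance of
107.6 L/h. Km values are interpreted as concentrations in µmol/L (the
source table prints "µmol"). The well-stirred liver model converts this to
a hepatic blood clearance of 38.5 L/h at a hepatic blood flow of 90 L/h —
an intermediate-extraction drug. Reference physiology (liver 1650 g, MPPGL
40 mg/g, hepatic flow 90 L/h at 70 kg) is configuration and is rescaled
per subject. Renal clearance defaults to zero (hepatic metabolism
dominates) behind a configuration hook.

The incubation unbound fraction can also be *estimated* from substrate
depletion data with `fit_fu_inc()`: bounded Nelder–Mead (start 0.3, bounds
(0,1) enforced by penalty, at most 100 iterations) on a weighted
least-squares objective with weights $1/\hat y^2$ — the settings under
which this parameter is conventionally fitted. A flat objective returns
the start value with an explicit non-convergence flag.

## Whole-body model

Eleven perfusion-limited organs plus arterial and venous blood, lungs in
series with the full cardiac output, venous-equilibrium convention
($C_{out} = C_t \cdot (B\!/\!P)/K_{p,t}$), and a liver receiving hepatic
artery, portal venous outflow of gut and spleen, and the absorption flux
from the enterocytes. Hepatic elimination acts on the unbound liver
concentration via $CLu_{int}$, which reproduces well-stirred behaviour at
steady state. The model is linear throughout: dose-proportionality and
single-dose/steady-state superposition hold to solver precision and are
asserted in the test suite.

## Virtual populations

Three transparent specifications (`healthy_adult`, `general_nec`,
`geriatric_nec`) stand in for proprietary population libraries, which are
deliberately **not** reproduced. All strictly positive quantities are
log-normal, truncated at ±3 SD; organ volumes scale linearly and flows
allometrically (exponent 0.75) with body weight. Age-related declines
beyond age 40 — liver mass −0.5%/yr, hepatic and systemic flows −0.3%/yr —
are applied deterministically and drive the geriatric exposure trend; only
the *direction* of that trend is treated as checkable, since the reference
populations are not quantitatively specified. Variability defaults: weight
CV 16%, liver mass CV 20%, MPPGL CV 30%, enzyme-abundance multiplier CV
35%. One global seed yields a per-subject seed sequence (drawn once with
`sample.int`), so cohorts are reproducible subject-by-subject and
extending a cohort leaves earlier subjects unchanged.

## Trial engine and verification

Titration regimens are simulated in full (each tablet is dropped into the
stomach by a solver event; overlapping release of consecutive tablets is
handled by superposing their Weibull rates), rather than assuming steady
state analytically — PK assessment windows fall on the last day of the
assessed dosing period, as in the underlying study designs.
Noncompartmental analysis uses the linear-up/log-down trapezoid (a plain
linear option exists), Cmax/Tmax by discrete maximum with earliest-time
tie-breaking, and $\lambda_z$ from the best adjusted-$R^2$ log-linear
window over the last 3–6 post-peak points; a non-estimable $\lambda_z$
flags AUC$_{0-\infty}$ as missing rather than failing the subject.
Verification computes the symmetric fold $\max(s/o, o/s)$ per metric with
the two-fold pass rule; mean, geometric-mean and median pairings are all
supported because observed reports differ in what they tabulate.

Observed clinical summaries are user-supplied CSVs — the underlying trial
reports are not public — so the package ships a clearly labelled
*synthetic* pseudo-observed fixture (generated by its own trial engine
plus multiplicative noise) to make the verification path testable
end-to-end.

## Synthetic data

All generators use multiplicative log-normal noise (dissolution readings
and concentrations are positive and right-skewed; one noise model keeps
the surface small), are bitwise reproducible per seed, and round-trip
through their paired estimators exactly at `cv = 0`. The default synthetic
trial fixture mirrors the most-exercised study design: n = 27, ages 47–81,
8 mg arm after 2/4/6/8 mg weekly titration.

## Numerical choices

* `lsoda` throughout, stiffness-switching, with `rtol = 1e-8`,
  `atol = 1e-10` defaults; doses are solver events, so the integrator
  restarts at each administration rather than stepping over a
  discontinuity.
* The coupled gut + body system has 52 states; right-hand sides are
  integer-indexed and allocation-light since they sit in the inner loop.
* Mass balance is asserted post hoc on every simulation (0.1% of dose)
  unless explicitly disabled.
* Output rows recorded exactly at an event time precede the event by
  deSolve convention; bookkeeping that compares state to administered dose
  accounts for this.

## Problem sizes

Routine checks run on reduced problem sizes chosen to exercise every code
path at interactive speed: dose-proportionality and superposition on a
5-subject cohort; dissolution-sensitivity and geriatric age-band
experiments on 5 and 10 subjects per arm/band; the acceptance summary
simulates the 8 mg titration design with 6 subjects and reports
population means. Full-size cohorts (n = 27–50) run in a few minutes each
with `simulate_trial()`.

## Known limitations

* No mechanistic dissolution (pH, diffusion layer, micelles), no
  precipitation, no fluid-volume dynamics; the Weibull input *is* the
  in-vivo release hypothesis being tested.
* Permeability-limited tissues, enzyme ontogeny, transporters and DDIs are
  out of scope; interspecies-scaled clearance is deliberately not
  implemented.
* Population specs are literature-typical, not calibrated to any
  proprietary library; absolute exposures in sampled populations carry
  that uncertainty even where the reference-subject predictions verify.
* The synthetic pseudo-observed data share the model's own structure;
  passing the two-fold check against them demonstrates the machinery, not
  clinical accuracy.
* Tmax of a prolonged-release steady-state profile is nearly flat, so
  noise moves the discrete maximum easily — Tmax folds are reported but
  are weak evidence either way.
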
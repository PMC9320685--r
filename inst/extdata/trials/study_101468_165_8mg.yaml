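# Study 101468/165, 8 mg arm: Parkinson's patients, titration 2/4/6/8 mg QD
# x 7 days, PK at the 8 mg steady state.
study_id: "101468_165_8mg"
drug: ropinirole
formulation:
  weibull:
    alpha: 34.02
    beta: 1.37
population: general_nec
n_subjects: 25
age_range: [47, 87]
male_fraction: 0.6
regimen:
  - {dose_mg: 2, interval_h: 24, n_doses: 7}
  - {dose_mg: 4, interval_h: 24, n_doses: 7}
  - {dose_mg: 6, interval_h: 24, n_doses: 7}
  - {dose_mg: 8, interval_h: 24, n_doses: 7}
pk_phase: 4
prandial: fasted
followup_h: 48
seed: 1
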
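# Study 101468/164 (fasted arm): Parkinson's patients, titration 2/4/6/8 mg
# QD x 7 days, PK at the 8 mg steady state.
study_id: "101468_164_fasted"
drug: ropinirole
formulation:
  weibull:
    alpha: 17.14
    beta: 1.08
population: general_nec
n_subjects: 21
age_range: [34, 80]
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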
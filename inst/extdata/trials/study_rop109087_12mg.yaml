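# Study ROP109087, 12 mg arm: Parkinson's patients, titration 2/4/6/8/12 mg
# QD x 7 days each, PK at the 12 mg steady state, fasted.
study_id: ROP109087_12mg
drug: ropinirole
formulation:
  weibull:
    alpha: 22.24
    beta: 1.19
population: general_nec
n_subjects: 27
age_range: [47, 81]
male_fraction: 0.6
regimen:
  - {dose_mg: 2, interval_h: 24, n_doses: 7}
  - {dose_mg: 4, interval_h: 24, n_doses: 7}
  - {dose_mg: 6, interval_h: 24, n_doses: 7}
  - {dose_mg: 8, interval_h: 24, n_doses: 7}
  - {dose_mg: 12, interval_h: 24, n_doses: 7}
pk_phase: 5
prandial: fasted
followup_h: 48
seed: 1
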
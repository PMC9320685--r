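# Study ROP109087, 8 mg arm: Parkinson's patients, titration 2/4/6/8 mg QD
# x 7 days each, PK assessed on the last day of the 8 mg period, fasted.
study_id: ROP109087_8mg
drug: ropinirole
formulation:
  weibull:
    alpha: 26.55
    beta: 1.22
population: general_nec
n_subjects: 27
age_range: [47, 81]
male_fraction: 0.6
regimen:
  - {dose_mg: 2, interval_h: 24, n_doses: 7}
  - {dose_mg: 4, interval_h: 24, n_doses: 7}
  - {dose_mg: 6, interval_h: 24, n_doses: 7}
  - {dose_mg: 8, interval_h: 24, n_doses: 7}
pk_phase: 4
prandial: fasted
followup_h: 48
sampling:
  dt_out: 0.25
solver:
  rtol: 1.0e-8
  atol: 1.0e-10
seed: 1
observed_csv: ../observed_synthetic_rop109087_8mg.csv
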
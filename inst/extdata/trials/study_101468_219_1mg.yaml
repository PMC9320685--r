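# Study 101468/219, 1 mg arm: healthy volunteers, single QD dose, fed.
study_id: "101468_219_1mg"
drug: ropinirole
formulation:
  weibull:
    alpha: 33.66
    beta: 1.34
population: healthy_adult
n_subjects: 32
age_range: [18, 44]
male_fraction: 0.5
regimen:
  - {dose_mg: 1, interval_h: 24, n_doses: 1}
prandial: fed
followup_h: 72
seed: 1
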
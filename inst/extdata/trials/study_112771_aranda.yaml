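# Study 112771 (Aranda site): healthy volunteers, single 2 mg dose, fasted.
study_id: "112771_aranda"
drug: ropinirole
formulation:
  weibull:
    alpha: 33.70
    beta: 1.33
population: healthy_adult
n_subjects: 50
age_range: [18, 50]
male_fraction: 0.5
regimen:
  - {dose_mg: 2, interval_h: 24, n_doses: 1}
prandial: fasted
followup_h: 72
seed: 1
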
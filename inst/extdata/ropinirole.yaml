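# Ropinirole model parameters (prolonged-release product reference set).
# Units: mw g/mol; permeabilities PAMPA 1e-6 cm/s; vmax nmol/h/mg
# microsomal protein; km umol/L.
mw: 260.38
logp: 2.7
compound_type: monoprotic_base
pka: 9.79
bp: 1.09
fu: 0.68
fu_mic: 0.39
papp_pampa: 26.8
pathways:
  - enzyme: CYP1A2
    pathway: N-despropylation
    vmax: 7.83
    km: 34.63
  - enzyme: CYP3A4
    pathway: N-despropylation
    vmax: 523.33
    km: 2700.00
  - enzyme: CYP1A2
    pathway: hydroxylation
    vmax: 6.93
    km: 45.87
  - enzyme: CYP3A4
    pathway: hydroxylation
    vmax: 255.33
    km: 3933.33
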
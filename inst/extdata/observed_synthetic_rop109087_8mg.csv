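"metric","value"
"cmax",8.15311
"tmax",2.75
"auc_0_tau",146.13
"auc_0_inf",236.492
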
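# canonical warm dense dark-cloud interior
temperature_K: 100
n_h2_cm3: 1.0e+7
fractional_abundance: 1.0e-7
uv_class: DC
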
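{
  "comment": "Monomer UV photolysis half-lives by environment class and measured peptide destruction quantum efficiencies.",
  "environments": [
    {"class": "DISM", "half_life_yr": 300},
    {"class": "DC", "half_life_yr": 3e7}
  ],
  "peptides": [
    {"species": "Gly-Trp", "wavelength_nm": 145, "quantum_efficiency": 1.3e-2},
    {"species": "Gly-Gly", "wavelength_nm": 206, "quantum_efficiency": 2.2e-2}
  ]
}
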
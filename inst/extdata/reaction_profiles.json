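{
  "comment": "Five-state condensation energy profiles, kJ/mol relative to separated reactants (state 1 = 0). Per-profile values are synthetic anchors within the stated typical values and ranges (binding -25 to -100, bound-water product ~ -50, water removal ~ +200, Gly-Gly barrier 200, glycol -40/290); every profile is flagged approximate.",
  "species": [
    {"name": "Gly", "atom_count": 10, "mass_u": 75.07, "kind": "amino_acid"},
    {"name": "Ala", "atom_count": 13, "mass_u": 89.09, "kind": "amino_acid"},
    {"name": "Glu", "atom_count": 19, "mass_u": 147.13, "kind": "amino_acid"},
    {"name": "Asp", "atom_count": 16, "mass_u": 133.10, "kind": "amino_acid"},
    {"name": "Ile", "atom_count": 22, "mass_u": 131.17, "kind": "amino_acid"},
    {"name": "Ser", "atom_count": 14, "mass_u": 105.09, "kind": "amino_acid"},
    {"name": "Leu", "atom_count": 22, "mass_u": 131.17, "kind": "amino_acid"},
    {"name": "Asn", "atom_count": 17, "mass_u": 132.12, "kind": "amino_acid"},
    {"name": "Pro", "atom_count": 17, "mass_u": 115.13, "kind": "amino_acid"},
    {"name": "Lys", "atom_count": 24, "mass_u": 146.19, "kind": "amino_acid"},
    {"name": "Phe", "atom_count": 23, "mass_u": 165.19, "kind": "amino_acid"},
    {"name": "EG", "atom_count": 10, "mass_u": 62.07, "kind": "glycol"},
    {"name": "H2O", "atom_count": 3, "mass_u": 18.02, "kind": "water"},
    {"name": "Gly-Gly", "atom_count": 20, "mass_u": 150.13, "kind": "polymer"},
    {"name": "Gly-Ala", "atom_count": 23, "mass_u": 164.16, "kind": "polymer"}
  ],
  "profiles": [
    {"pair": ["Glu", "Ala"], "conformer": 1, "e_pair": -60, "e_ts": 25, "e4": -50, "e5": 150, "approximate": true},
    {"pair": ["Asp", "Ile"], "conformer": 1, "e_pair": -65, "e_ts": 10, "e4": -52, "e5": 148, "approximate": true},
    {"pair": ["Ser", "Leu"], "conformer": 1, "e_pair": -55, "e_ts": 40, "e4": -48, "e5": 155, "approximate": true},
    {"pair": ["Asn", "Pro"], "conformer": 1, "e_pair": -75, "e_ts": -5, "e4": -55, "e5": 145, "approximate": true},
    {"pair": ["Lys", "Phe"], "conformer": 1, "e_pair": -60, "e_ts": 120, "e4": -50, "e5": 150, "approximate": true},
    {"pair": ["Phe", "Gly"], "conformer": 1, "e_pair": -50, "e_ts": 150, "e4": -46, "e5": 158, "approximate": true},
    {"pair": ["Phe", "Gly"], "conformer": 2, "e_pair": -40, "e_ts": 185, "e4": -50, "e5": 152, "approximate": true},
    {"pair": ["Ala", "Ala"], "conformer": 1, "e_pair": -30, "e_ts": 250, "e4": -45, "e5": 160, "approximate": true},
    {"pair": ["Ala", "Ala"], "conformer": 2, "e_pair": -90, "e_ts": 300, "e4": -55, "e5": 142, "approximate": true},
    {"pair": ["Gly", "Gly"], "conformer": 1, "e_pair": -60, "e_ts": 200, "e4": -50, "e5": 150, "approximate": true},
    {"pair": ["Gly", "Gly"], "conformer": 2, "e_pair": -58, "e_ts": 235, "e4": -49, "e5": 153, "approximate": true},
    {"pair": ["Ala", "Gly"], "conformer": 1, "e_pair": -55, "e_ts": 165, "e4": -51, "e5": 149, "approximate": true},
    {"pair": ["Ile", "Gly"], "conformer": 1, "e_pair": -62, "e_ts": 95, "e4": -50, "e5": 151, "approximate": true},
    {"pair": ["Ile", "Gly"], "conformer": 2, "e_pair": -68, "e_ts": 110, "e4": -53, "e5": 147, "approximate": true},
    {"pair": ["EG", "EG"], "conformer": 1, "e_pair": -40, "e_ts": 290, "e4": -30, "e5": null, "approximate": true},
    {"pair": ["EG", "EG"], "conformer": 2, "e_pair": -40, "e_ts": 290, "e4": -28, "e5": null, "approximate": true},
    {"pair": ["EG", "EG"], "conformer": 3, "e_pair": -42, "e_ts": 290, "e4": -32, "e5": null, "approximate": true},
    {"pair": ["EG", "EG"], "conformer": 4, "e_pair": -38, "e_ts": 290, "e4": -29, "e5": null, "approximate": true},
    {"pair": ["EG", "EG"], "conformer": 5, "e_pair": -40, "e_ts": 0, "e4": 10, "e5": null, "approximate": true},
    {"pair": ["EG", "EG"], "conformer": 6, "e_pair": -41, "e_ts": 0, "e4": 12, "e5": null, "approximate": true},
    {"pair": ["EG", "EG"], "conformer": 7, "e_pair": -39, "e_ts": 0, "e4": 8, "e5": null, "approximate": true},
    {"pair": ["Gly-Gly", "Gly-Ala"], "conformer": 1, "e_pair": -70, "e_ts": 40, "e4": -65, "e5": 140, "approximate": true}
  ]
}
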
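{
  "comment": "Synthetic electronegativity-equalization parameter table. Hand-chosen plausible constants (electronegativity ordering F > O > Cl > N > Br > I > S > C > H); NOT fitted to any quantum-chemical source. Units are arbitrary energy/charge (e0) and energy/charge^2 (s0); de_per_charge shifts e0 per unit of delocalized formal charge.",
  "version": "qeqnet-eem-synthetic-1",
  "elements": ["H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I"],
  "e0":            [2.20, 2.55, 3.04, 3.44, 2.58, 2.19, 3.98, 3.16, 2.96, 2.66],
  "s0":            [6.40, 5.00, 7.20, 6.10, 4.10, 4.90, 7.00, 4.70, 4.20, 3.70],
  "de_per_charge": [-1.80, -2.00, -2.20, -2.40, -2.00, -1.90, -2.60, -2.20, -2.00, -1.80]
}
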
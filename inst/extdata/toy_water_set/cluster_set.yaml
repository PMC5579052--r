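name: toy_water
monomer:
  label: H2O
  mass: 18.01529999999999987
  molar_mass: 18.01529999999999987
clusters:
- label: W1
  n_monomers: 1
  n_hydronium: 0
  n_hydroxide: 0
  energy: 0.0
  energy_unit: kJ/mol
  volume: 19.60000000000000142
  sigma: 2
  rotational_constants:
  - 835.79999999999995453
  - 435.10000000000002274
  - 278.39999999999997726
  frequencies_file: W1.freq
  geometry_file: W1.xyz
- label: W3c
  n_monomers: 3
  n_hydronium: 0
  n_hydroxide: 0
  energy: -66.0
  energy_unit: kJ/mol
  volume: 58.39999999999999858
  sigma: 1
  rotational_constants:
  - 6.71999999999999975
  - 6.58000000000000007
  - 3.41000000000000014
  frequencies_file: W3c.freq
- label: W5c
  n_monomers: 5
  n_hydronium: 0
  n_hydroxide: 0
  energy: -151.0
  energy_unit: kJ/mol
  volume: 96.5
  sigma: 1
  rotational_constants:
  - 1.82000000000000006
  - 1.70999999999999996
  - 0.93999999999999995
  frequencies_file: W5c.freq
- label: W5ip
  n_monomers: 5
  n_hydronium: 1
  n_hydroxide: 1
  energy: -71.0
  energy_unit: kJ/mol
  volume: 94.79999999999999716
  sigma: 1
  rotational_constants:
  - 1.87999999999999989
  - 1.76000000000000001
  - 0.97999999999999998
  frequencies_file: W5ip.freq
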
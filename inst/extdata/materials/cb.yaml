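name: cb
label: Cacao-based breakfast-cereal recipe (CB)
provenance: 'Viscosity parameters: published calibration table. Melting curve and
  thermal properties: reconstructed, editable (anchored to published points where
  printed). Melting curve anchored: T_m = 165 C at MC = 0.15.'
composition:
  starch: 0.727
  protein: 0.063
  fiber: 0.013
  lipid: 0.028
  ash: 0.008
  sugar: 0.1
  salt: 0.01
  amylose_of_starch: 0.24
thermal:
  cp_dry_J_kgK: 1500.0
  cp_water_J_kgK: 4186.0
  rho_dry_kg_m3: 1400.0
  rho_water_kg_m3: 1000.0
  k_dry_W_mK: 0.25
  k_water_W_mK: 0.6
  melting_enthalpy_J_kg: 10000.0
melting_curve:
  MC:
  - 0.1
  - 0.15
  - 0.19
  - 0.23
  - 0.3
  - 0.4
  T_C:
  - 185.0
  - 165.0
  - 150.0
  - 138.0
  - 122.0
  - 108.0
viscosity:
  dialect: referenced
  K0_Pasn: 1710000.0
  E_over_R_K: 6765.0
  alpha: 13.6
  beta: 0.0
  n0: 0.0
  a1: 0.00328
  a2: -2.18
  a3: 0.0
  a4: 0.00805
  a5: 0.0
  a6: 0.0
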
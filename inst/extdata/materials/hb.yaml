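name: hb
label: Honey/malt-based breakfast-cereal recipe (HB)
provenance: 'Viscosity parameters: published calibration table. Melting curve and
  thermal properties: reconstructed, editable (anchored to published points where
  printed). Melting curve anchored: T_m = 133 C at MC = 0.15.'
composition:
  starch: 0.823
  protein: 0.046
  fiber: 0.0052
  lipid: 0.014
  ash: 0.0017
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
  melting_enthalpy_J_kg: 11500.0
melting_curve:
  MC:
  - 0.1
  - 0.15
  - 0.19
  - 0.23
  - 0.3
  - 0.4
  T_C:
  - 151.0
  - 133.0
  - 121.0
  - 111.0
  - 99.0
  - 88.0
viscosity:
  dialect: referenced
  K0_Pasn: 12200000.0
  E_over_R_K: 11153.0
  alpha: 13.7
  beta: 0.0
  n0: 0.0
  a1: 0.0037
  a2: -2.55
  a3: 0.0
  a4: 0.0095
  a5: 0.0
  a6: 0.0
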
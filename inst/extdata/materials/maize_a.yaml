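name: maize_a
label: High-amylose maize starch (70% amylose)
provenance: 'Viscosity parameters: published calibration table. Melting curve and
  thermal properties: reconstructed, editable (anchored to published points where
  printed).'
composition:
  starch: 0.934
  protein: 0.0015
  fiber: 0.01
  lipid: 0.013
  ash: 0.0015
  amylose_of_starch: 0.7
thermal:
  cp_dry_J_kgK: 1500.0
  cp_water_J_kgK: 4186.0
  rho_dry_kg_m3: 1400.0
  rho_water_kg_m3: 1000.0
  k_dry_W_mK: 0.25
  k_water_W_mK: 0.6
  melting_enthalpy_J_kg: 13000.0
melting_curve:
  MC:
  - 0.1
  - 0.15
  - 0.2
  - 0.25
  - 0.3
  - 0.4
  T_C:
  - 205.0
  - 185.0
  - 167.0
  - 152.0
  - 140.0
  - 120.0
viscosity:
  dialect: referenced
  K0_Pasn: 12100000.0
  E_over_R_K: 11440.0
  alpha: 14.6
  beta: 0.0
  n0: -1.16
  a1: 0.00793
  a2: 1.31
  a3: 0.0
  a4: 0.0
  a5: 0.0
  a6: 0.0
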
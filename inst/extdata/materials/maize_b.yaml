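name: maize_b
label: Maize starch blend A/D = 2/1 (47% amylose)
provenance: 'Viscosity parameters: published calibration table. Melting curve and
  thermal properties: reconstructed, editable (anchored to published points where
  printed).'
composition:
  starch: 0.93
  protein: 0.0018
  fiber: 0.01
  lipid: 0.011
  ash: 0.0013
  amylose_of_starch: 0.47
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
  - 192.0
  - 172.0
  - 154.0
  - 140.0
  - 128.0
  - 110.0
viscosity:
  dialect: referenced
  K0_Pasn: 1910000.0
  E_over_R_K: 7983.0
  alpha: 17.9
  beta: 7.44e-05
  n0: 1.81
  a1: -0.00736
  a2: -1.93
  a3: -0.00489
  a4: 0.0
  a5: 1.98e-05
  a6: 0.00919
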
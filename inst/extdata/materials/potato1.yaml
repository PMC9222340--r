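name: potato1
label: Potato starch
provenance: 'Viscosity parameters: published calibration table. Melting curve and
  thermal properties: reconstructed, editable (anchored to published points where
  printed).'
composition:
  starch: 0.957
  protein: 0.0008
  fiber: 0.01
  lipid: 0.0006
  ash: 0.006
  amylose_of_starch: 0.21
thermal:
  cp_dry_J_kgK: 1500.0
  cp_water_J_kgK: 4186.0
  rho_dry_kg_m3: 1400.0
  rho_water_kg_m3: 1000.0
  k_dry_W_mK: 0.25
  k_water_W_mK: 0.6
  melting_enthalpy_J_kg: 13400.0
melting_curve:
  MC:
  - 0.1
  - 0.15
  - 0.2
  - 0.25
  - 0.3
  - 0.4
  T_C:
  - 175.0
  - 155.0
  - 140.0
  - 127.0
  - 117.0
  - 100.0
viscosity:
  dialect: referenced
  K0_Pasn: 3670000.0
  E_over_R_K: 6421.0
  alpha: 14.9
  beta: 0.00308
  n0: 0.01
  a1: 0.00155
  a2: 0.0996
  a3: 0.000275
  a4: 0.153
  a5: -3.47e-05
  a6: -1.27e-07
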
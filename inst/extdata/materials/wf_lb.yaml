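name: wf_lb
label: Wheat flour + low bran content (WF-LB)
provenance: 'Viscosity parameters: published calibration table. Melting curve and
  thermal properties: reconstructed, editable (anchored to published points where
  printed).'
composition:
  starch: 0.697
  protein: 0.139
  fiber: 0.126
  lipid: 0.016
  ash: 0.018
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
  - 0.18
  - 0.22
  - 0.3
  - 0.4
  T_C:
  - 180.0
  - 160.0
  - 150.0
  - 139.0
  - 121.0
  - 104.0
viscosity:
  dialect: absolute
  K0_Pasn: 0.16
  E_over_R_K: 7553.0
  alpha: 27.4
  beta: 0.00194
  n0: 0.165
  a1: 0.0
  a2: 0.0
  a3: 0.0
  a4: 0.0
  a5: 0.0
  a6: 0.0
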
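name: pf
label: Pea flour (PF)
provenance: 'Viscosity parameters: published calibration table. Melting curve and
  thermal properties: reconstructed, editable (anchored to published points where
  printed). Also a surrogate for pea starch and fava bean flour (close master curves);
  fava bean starch concentrate is approached by maize_b (47% amylose surrogacy rule).'
composition:
  starch: 0.463
  protein: 0.239
  fiber: 0.257
  lipid: 0.02
  ash: 0.021
  amylose_of_starch: 0.35
thermal:
  cp_dry_J_kgK: 1500.0
  cp_water_J_kgK: 4186.0
  rho_dry_kg_m3: 1400.0
  rho_water_kg_m3: 1000.0
  k_dry_W_mK: 0.25
  k_water_W_mK: 0.6
  melting_enthalpy_J_kg: 6500.0
melting_curve:
  MC:
  - 0.1
  - 0.15
  - 0.18
  - 0.21
  - 0.26
  - 0.4
  T_C:
  - 178.0
  - 160.0
  - 150.0
  - 142.0
  - 131.0
  - 108.0
viscosity:
  dialect: referenced
  K0_Pasn: 810000.0
  E_over_R_K: 4210.0
  alpha: 11.4
  beta: 0.0
  n0: 0.29
  a1: 0.0
  a2: 0.0
  a3: 0.0
  a4: 0.0
  a5: 0.0
  a6: 0.0
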
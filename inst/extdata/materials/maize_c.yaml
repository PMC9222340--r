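name: maize_c
label: Maize starch blend A/D = 1/1 (23.5% amylose)
provenance: 'Viscosity parameters: published calibration table. Melting curve and
  thermal properties: reconstructed, editable (anchored to published points where
  printed).'
composition:
  starch: 0.929
  protein: 0.002
  fiber: 0.01
  lipid: 0.0067
  ash: 0.0013
  amylose_of_starch: 0.235
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
  - 183.0
  - 163.0
  - 146.0
  - 132.0
  - 121.0
  - 104.0
viscosity:
  dialect: referenced
  K0_Pasn: 45700000.0
  E_over_R_K: 10850.0
  alpha: 29.5
  beta: 0.00106
  n0: 3.54
  a1: -0.0154
  a2: -3.19
  a3: -0.00872
  a4: 0.0
  a5: 4.1e-05
  a6: 0.0112
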
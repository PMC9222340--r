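machine:
  name: bc45_like
  screw_diameter_mm: 55.5
  centerline_distance_mm: 46.065
  total_length_mm: 1000.0
  elements:
  - kind: conveying_rh
    length_mm: 690.0
    channel_depth_mm: 8.9
    flight_count: 2
    flight_width_mm: 4.0
    flight_gap_mm: 0.25
    leak_depth_frac: 0.5
    shear_efficiency: 1.0
    ht_factor: 1.0
    pitch_mm: 50.0
  - kind: reverse_lh
    length_mm: 50.0
    channel_depth_mm: 8.9
    flight_count: 2
    flight_width_mm: 2.24
    flight_gap_mm: 0.25
    leak_depth_frac: 0.6
    shear_efficiency: 1.0
    ht_factor: 1.0
    pitch_mm: 28.0
  - kind: conveying_rh
    length_mm: 260.0
    channel_depth_mm: 8.9
    flight_count: 2
    flight_width_mm: 4.0
    flight_gap_mm: 0.25
    leak_depth_frac: 0.5
    shear_efficiency: 1.0
    ht_factor: 1.0
    pitch_mm: 50.0
  die:
  - kind: circular
    length_mm: 20.0
    radius_mm: 2.0
    group: 1.0
  - kind: circular
    length_mm: 20.0
    radius_mm: 2.0
    group: 1.0
  barrel_zones:
  - length_mm: 200.0
    temp_C: 20.0
  - length_mm: 200.0
    temp_C: 60.0
  - length_mm: 200.0
    temp_C: 90.0
  - length_mm: 200.0
    temp_C: 120.0
  - length_mm: 200.0
    temp_C: 120.0
operating:
  screw_speed_rpm: 500.0
  feed_rate_kg_h: 15.0
  moisture: 0.2
  barrel_temps_C:
  - 20.0
  - 60.0
  - 90.0
  - 120.0
  - 120.0
  nusselt: 20.0
material: maize_b
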
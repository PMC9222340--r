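machine:
  name: evolum25_like
  screw_diameter_mm: 25.0
  centerline_distance_mm: 20.75
  total_length_mm: 400.0
  elements:
  - kind: conveying_rh
    length_mm: 255.0
    channel_depth_mm: 4.0
    flight_count: 2
    flight_width_mm: 2.0
    flight_gap_mm: 0.25
    leak_depth_frac: 0.5
    shear_efficiency: 1.0
    ht_factor: 1.0
    pitch_mm: 25.0
  - kind: kneading_block
    length_mm: 25.0
    channel_depth_mm: 4.0
    flight_count: 2
    flight_width_mm: 1.0
    flight_gap_mm: 0.5
    leak_depth_frac: 0.25
    shear_efficiency: 0.5
    ht_factor: 1.0
    stagger_angle_deg: 45.0
    disc_thickness_mm: 6.25
  - kind: reverse_lh
    length_mm: 20.0
    channel_depth_mm: 4.0
    flight_count: 2
    flight_width_mm: 1.0
    flight_gap_mm: 0.25
    leak_depth_frac: 0.6
    shear_efficiency: 1.0
    ht_factor: 1.0
    pitch_mm: 12.5
  - kind: conveying_rh
    length_mm: 100.0
    channel_depth_mm: 4.0
    flight_count: 2
    flight_width_mm: 2.0
    flight_gap_mm: 0.25
    leak_depth_frac: 0.5
    shear_efficiency: 1.0
    ht_factor: 1.0
    pitch_mm: 25.0
  die:
  - kind: circular
    length_mm: 15.0
    radius_mm: 1.5
  barrel_zones:
  - length_mm: 100.0
    temp_C: 20.0
  - length_mm: 100.0
    temp_C: 60.0
  - length_mm: 100.0
    temp_C: 90.0
  - length_mm: 100.0
    temp_C: 90.0
operating:
  screw_speed_rpm: 600.0
  feed_rate_kg_h: 20.0
  moisture: 0.22
  barrel_temps_C:
  - 20.0
  - 60.0
  - 90.0
  - 140.0
  nusselt: 20.0
material: wf_lb
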
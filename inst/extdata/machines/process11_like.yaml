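machine:
  name: process11_like
  screw_diameter_mm: 11.0
  centerline_distance_mm: 9.13
  total_length_mm: 269.5
  elements:
  - kind: conveying_rh
    length_mm: 170.0
    channel_depth_mm: 1.8
    flight_count: 2
    flight_width_mm: 0.88
    flight_gap_mm: 0.25
    leak_depth_frac: 0.5
    shear_efficiency: 1.0
    ht_factor: 1.0
    pitch_mm: 11.0
  - kind: kneading_block
    length_mm: 11.0
    channel_depth_mm: 1.8
    flight_count: 2
    flight_width_mm: 0.88
    flight_gap_mm: 0.3
    leak_depth_frac: 0.5
    shear_efficiency: 0.5
    ht_factor: 1.0
    stagger_angle_deg: 90.0
    disc_thickness_mm: 2.75
  - kind: kneading_block
    length_mm: 11.0
    channel_depth_mm: 1.8
    flight_count: 2
    flight_width_mm: 0.88
    flight_gap_mm: 0.3
    leak_depth_frac: 0.5
    shear_efficiency: 0.5
    ht_factor: 1.0
    stagger_angle_deg: 90.0
    disc_thickness_mm: 2.75
  - kind: reverse_lh
    length_mm: 11.0
    channel_depth_mm: 1.8
    flight_count: 2
    flight_width_mm: 0.44
    flight_gap_mm: 0.25
    leak_depth_frac: 0.6
    shear_efficiency: 1.0
    ht_factor: 1.0
    pitch_mm: 5.5
  - kind: conveying_rh
    length_mm: 66.5
    channel_depth_mm: 1.8
    flight_count: 2
    flight_width_mm: 0.88
    flight_gap_mm: 0.25
    leak_depth_frac: 0.5
    shear_efficiency: 1.0
    ht_factor: 1.0
    pitch_mm: 11.0
  die:
  - kind: circular
    length_mm: 10.0
    radius_mm: 1.0
  barrel_zones:
  - length_mm: 53.9
    temp_C: 20.0
  - length_mm: 53.9
    temp_C: 60.0
  - length_mm: 53.9
    temp_C: 95.0
  - length_mm: 53.9
    temp_C: 95.0
  - length_mm: 53.9
    temp_C: 95.0
operating:
  screw_speed_rpm: 120.0
  feed_rate_kg_h: 1.0
  moisture: 0.3
  barrel_temps_C:
  - 20.0
  - 60.0
  - 95.0
  - 95.0
  - 95.0
  nusselt: 20.0
material: potato1
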
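# Reference chamber configuration: 1 MHz flat immersion transducer,
# 26.5 degree incidence, 1.2 mm glass slide, 15 um sample gap, 0.17 mm glass
# coverslip, air backing, 500 kPa free-field focal calibration.
transducer:
  geometry: flat
  element_radius_mm: 9.43
  external_radius_mm: 12.5
  frequency_mhz: 1.0
  focal_distance_mm: 60
calibration:
  focal_pressure_kpa: 500
chamber:
  incidence_angle_deg: 26.5
  bath: water
  slide:
    material: glass
    thickness_um: 1200
  sample:
    medium: water
    gap_um: 15
  coverslip:
    material: glass
    thickness_um: 170
  backing: air
  gap_range_um: [10, 20]
bubble:
  radius_um: 3
  gamma: 1.07
  hydrostatic_pressure_kpa: 101.325
  surface_tension_n_m: 0.072
  shell_elasticity_n_m: 0.55
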
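coil:
  n_turns: 8
  inner_radius: 25 mm
  axial_pitch: 6.8571428571428577 mm
  wire_radius: 2 mm
  frequency: 400000.0
probe_coil:
  diameter: 7.2999999999999998 mm
  n_turns: 2.5
  height: 30 mm
scaffold:
  diameter: 20 mm
  height: 20 mm
  center_offset:
  - 0 mm
  - 0 mm
  - 0 mm
phantom:
  diameter: 25 mm
  height: 40 mm
  center_offset:
  - 0 mm
  - 0 mm
  - 0 mm
materials:
  scaffold:
    rel_permittivity: 3.0
    conductivity: 1.0e-05
    thermal_conductivity: 0.47
    specific_heat: 1.2
    density: 2.7
  phantom:
    rel_permittivity: 70.0
    conductivity: 0.2
    thermal_conductivity: 0.48
    specific_heat: 4.2
    density: 1.0
exposure:
  target_flux_density: 30 mT
  frequency: 400000.0
  duration: 900.0
  field_off_time: 600.0
  ambient_temperature: 19.0
  convective_coeff_air: 10.0
  medium_mode: agar
solver:
  resolution: 2 mm
  dt: 0.1
  store_every: 60.0
probes:
  positions:
    C:
    - 0 mm
    - 0 mm
    - 0 mm
    L:
    - -7 mm
    - 0 mm
    - 0 mm
    R:
    - 7 mm
    - 0 mm
    - 0 mm
    T:
    - 0 mm
    - 0 mm
    - 9 mm
    O:
    - 0 mm
    - 0 mm
    - 20 mm
  sampling_rate: 1.0
  noise_sd: 0.1
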
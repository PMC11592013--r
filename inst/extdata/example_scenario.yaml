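# Example impact scenario: the calibrated default cavity strip at 15 km/h.
# Run with:  Rscript inst/cli/osteoimpact.R run --config example_scenario.yaml --out out15
mesh:
  kind: plate
  span: 48
  width: 16
  cortical_thickness: 1.5
  core_thickness: 1
  elem_size: 1.1
  support: abutments
  abutment_width: 10
impactor:
  length: 200
  diameter: 40
  mass_kg: 2
  speed_kmh: 15
contact:
  c0_mm: 1.5
  p0_MPa: 100
  mu: 0.2
simulation:
  duration: 5.0e-3
  dt_target: 1.0e-7
  output_interval: 1.0e-5
  snapshot_interval: 1.0e-3
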
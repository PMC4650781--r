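# Default braggmap pipeline configuration: monoenergetic 79.7 MeV
# scanned beam, 12-step Lucite jig with three 268-um films and a 1-mm
# plate bottom, reconstructed setup tolerances, synthetic H460 design.
beam:
  nominal_energy_MeV: 79.7
  range_water_cm: 4.8
  energy_spread_sigma_MeV: 0.545   # calibrated: peak/entrance column dose ~5.5
  range_straggling_frac: 0.012
  spot_fwhm_cm: 3.3                # 3.5 also quoted for the uniformity scan
  spot_spacing_cm: 1.0
  dose_per_painting_cGy: 2.6
  mu_per_painting: 17.64
jig:
  # step_thickness_cm: omit to design from the default LET targets
  n_films: 3
  film_thickness_um: 268
  plate_bottom_cm: 0.1             # not published; working default
  cell_layer_um: 5
tolerances:                        # reconstructed defaults
  step_cm: 0.0003                  # +/- 3 um milling accuracy
  film_frac: 0.01                  # vendor spec ~1%
  plate_bottom_cm: 0.005           # +/- 50 um moulding variability
  density_frac: 0.005
design:
  cell_line: H460
  seeded_per_well: 100
  plating_efficiency: 0.8          # not published; explicit configuration
  dose_levels_Gy: [0.0, 0.5, 1.0, 2.0, 4.0, 6.0]
  plates_per_dose: 2
analysis:
  survival_level: 0.10
seed: 1
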
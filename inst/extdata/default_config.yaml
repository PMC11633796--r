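phantom:
  body_size_mm:
  - 190.0
  - 310.0
  thickness_mm: 41.0
  wax_block_size_mm:
  - 60.0
  - 90.0
  wax_block_offset_mm:
  - 17.0
  - 110.0
  speck_spacing_mm: 2.0
  fiber_length_mm: 8.0
  mass_diameter_mm: 3.0
  objects:
  - kind: fiber
    index: 1
    size_mm: 0.8
    center_mm:
    - 10.0
    - 7.5
    orientation_deg: 45.0
  - kind: fiber
    index: 2
    size_mm: 0.698569967862919
    center_mm:
    - 10.0
    - 22.5
    orientation_deg: 135.0
  - kind: fiber
    index: 3
    size_mm: 0.61
    center_mm:
    - 10.0
    - 37.5
    orientation_deg: 45.0
  - kind: fiber
    index: 4
    size_mm: 0.497039842857337
    center_mm:
    - 10.0
    - 52.5
    orientation_deg: 135.0
  - kind: fiber
    index: 5
    size_mm: 0.40499771375024
    center_mm:
    - 10.0
    - 67.5
    orientation_deg: 45.0
  - kind: fiber
    index: 6
    size_mm: 0.33
    center_mm:
    - 10.0
    - 82.5
    orientation_deg: 135.0
  - kind: speck_group
    index: 1
    size_mm: 0.33
    center_mm:
    - 30.0
    - 7.5
    speck_spacing_mm: 2.0
    n_specks: 6
  - kind: speck_group
    index: 2
    size_mm: 0.277994855490702
    center_mm:
    - 30.0
    - 22.5
    speck_spacing_mm: 2.0
    n_specks: 6
  - kind: speck_group
    index: 3
    size_mm: 0.234185271755444
    center_mm:
    - 30.0
    - 37.5
    speck_spacing_mm: 2.0
    n_specks: 6
  - kind: speck_group
    index: 4
    size_mm: 0.197279699332441
    center_mm:
    - 30.0
    - 52.5
    speck_spacing_mm: 2.0
    n_specks: 6
  - kind: speck_group
    index: 5
    size_mm: 0.166190125779307
    center_mm:
    - 30.0
    - 67.5
    speck_spacing_mm: 2.0
    n_specks: 6
  - kind: speck_group
    index: 6
    size_mm: 0.14
    center_mm:
    - 30.0
    - 82.5
    speck_spacing_mm: 2.0
    n_specks: 6
  - kind: mass
    index: 1
    size_mm: 1.0
    center_mm:
    - 50.0
    - 7.5
  - kind: mass
    index: 2
    size_mm: 0.724779663677696
    center_mm:
    - 50.0
    - 22.5
  - kind: mass
    index: 3
    size_mm: 0.525305560880754
    center_mm:
    - 50.0
    - 37.5
  - kind: mass
    index: 4
    size_mm: 0.380730787743176
    center_mm:
    - 50.0
    - 52.5
  - kind: mass
    index: 5
    size_mm: 0.275945932292243
    center_mm:
    - 50.0
    - 67.5
  - kind: mass
    index: 6
    size_mm: 0.2
    center_mm:
    - 50.0
    - 82.5
smoothing:
  sigma_mm: 0.1
localization:
  dim_tol_frac: 0.1
  area_tol_frac: 0.25
  closing_mm: 2.0
  border_px: 2
thresholds:
  fiber:
    gamma_zero: 0.5
    gamma_partial: 0.5
    gamma_full: 0.65
    binarize_frac: 0.6
    angle_tol_deg: 4.0
  speck_group:
    gamma_zero: 0.18
    peak_threshold: 0.3
    min_rel_amplitude: 0.35
    spacing_tol_frac: 0.3
  mass:
    gamma_zero: 0.5
    gamma_partial: 0.5
    gamma_full: 0.78
    fwhm_band:
    - 0.5
    - 1.8
    centroid_tol_px_50um: 5.0
chest_wall_default: left

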
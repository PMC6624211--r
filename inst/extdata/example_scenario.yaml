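window_width_km: 60.0
window_height_km: 60.0
road_specs:
  road_class:
  - primary
  - secondary
  - tertiary
  n_segments:
  - 4
  - 8
  - 15
habitat_specs:
  suitability:
  - highly_suitable
  - suitable
  n_patches:
  - 3
  - 4
  radius_km:
  - 5.0
  - 6.0
intensity_intercept_alpha: ~
intensity_slope_beta:
  primary: -1.469675970058942
  secondary: -1.237874356001617
  tertiary: -0.843970070294529
target_n: 3000.0
seasonal_profile:
- 0.062176165803109
- 0.05699481865285
- 0.051813471502591
- 0.051813471502591
- 0.05699481865285
- 0.067357512953368
- 0.088082901554404
- 0.10880829015544
- 0.134715025906736
- 0.134715025906736
- 0.10880829015544
- 0.077720207253886
attribute_probs:
  sex:
    male: 0.218527990906508
    female: 0.222648479681728
    unknown: 0.558823529411765
  age_class:
    adult: 0.831770389315146
    subadult: 0.114734299516908
    young: 0.007388462631429
    unknown: 0.046106848536516
  physical_location:
    tree: 0.787865870986076
    ground: 0.055626598465473
    other: 0.061167945439045
    unknown: 0.095339585109406
  status:
    alive_sighting: 0.85
    injured: 0.06
    dead: 0.07
    euthanized: 0.02
n_years: 17
start_year: 1997
reporters_per_year: ~
duplicate_fraction: 0.02
corrupt_fraction: 0.01
seed: 1
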
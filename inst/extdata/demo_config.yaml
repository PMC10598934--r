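seed: 2.0260903e+07
input:
  simulate:
    n_pairs: 371
    traits:
    - light_areas
    - bright_areas
    paths:
      light_areas->bright_areas: 0.7073171
    familial_loading:
      light_areas: 0.543139
      bright_areas: 0.2320002
    unique_sd:
      light_areas: 0.6403124
      bright_areas: 0.514663
    confounders:
      shared:
        light_areas: 0.543139
        bright_areas: 0.1890546
    age_range:
    - 40.0
    - 70.0
    age_slope:
      light_areas: -0.0164683
      bright_areas: -0.0362533
    age_jitter_sd: 0.5
    raw_transforms:
      light_areas:
        power: 3.0
        offset: 0.0
        center: 2.59
        scale: 0.59
      bright_areas:
        power: 3.0
        offset: 0.0
        center: 2.07
        scale: 0.42
    stratifier:
      loadings:
        light_areas: 0.7
        bright_areas: 0.3
      noise_sd: 0.5
      mean: 30.5
      scale: 8.0
    seed: 20260901
traits:
- light_areas
- bright_areas
covariates: age
B: 400.0
alpha: 0.05
analyses:
- predictor: light_areas
  outcome: bright_areas
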
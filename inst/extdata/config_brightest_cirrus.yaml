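n_pairs: 371
traits:
- brightest_areas
- cirrus
paths:
  brightest_areas->cirrus: 0.2272727
familial_loading:
  brightest_areas: 0.4123106
  cirrus: 0.3585168
unique_sd:
  brightest_areas: 0.8124038
  cirrus: 0.6970718
confounders:
  shared:
    brightest_areas: 0.4123106
    cirrus: 0.4916859
age_range:
- 40.0
- 70.0
age_slope:
  brightest_areas: -0.038426
  cirrus: -0.038426
age_jitter_sd: 0.5
raw_transforms:
  brightest_areas:
    power: 5.0
    offset: 0.0
    center: 1.1
    scale: 0.23
  cirrus:
    power: 0.5
    offset: 2907.0
    center: 11.56
    scale: 3.66
stratifier: ~
seed: 20260902
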
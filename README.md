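# icefalcon

Causal decomposition of twin-pair associations with the ICE FALCON
procedure (Inference about Causation from Examination of FAmilial
CONfounding), built around mammogram-based breast cancer risk scores but
usable for any continuous traits measured on complete monozygotic twin
pairs.

Correlated risk measures — the light, bright and brightest dense areas of
a mammogram, or an automated texture score such as Cirrus — may be linked
because one causes the other or because familial factors (genes, shared
environment) influence both. With MZ pairs the two explanations leave
different fingerprints. For predictor score *X* and outcome score *Y* on
double-entered pair data, three marginal regressions are fitted by GEE
with cluster-robust errors:

- Model 1: `Y_self = β_self · X_self + ε₁`
- Model 2: `Y_self = β_cotwin · X_cotwin + ε₂`
- Model 3: `Y_self = β'_self · X_self + β'_cotwin · X_cotwin + ε₃`

Causation collapses `β'_cotwin` towards zero while `β'_self` stays put;
familial confounding attenuates both coefficients by a similar fraction.
With `Δβ = β − β'` and `ρ` the within-pair correlation of the predictor
score, path tracing splits the association:

```
Pr = ((Δβ_cotwin − (Δβ_self / β_self) · β_cotwin) / ρ) / β_self
```

`Pr` is the causal fraction of the Model 1 association, `β_self · Pr` the
causal effect size, and `1 − Pr` the familial-confounding fraction.

The package provides the full pipeline: Box–Cox normalisation and age
adjustment of raw measures into standardised risk scores
(`risk_scores()`), the twin correlation table (`twin_correlations()`),
double-entry GEE fits (`fit_models()`), cluster-bootstrap tests for the
coefficient changes (`bootstrap_changes()`), the decomposition and
decision rules (`decompose()`, `infer_conclusion()`,
`run_pair_analysis()`), median-split stratified analyses, a causal-diagram
export (DOT/JSON), and a calibrated linear-structural twin simulator with
exact closed-form population moments (`simulate_pairs()`,
`theoretical_coefficients()`) that serves as the oracle for every
estimator in the test suite.

## Worked example

Reported coefficient tables can be decomposed directly, without refitting.
The shipped `worked_example.yaml` carries the three-model coefficients of
a published MZ-twin analysis of four mammogram risk scores (371 pairs):

```r
library(icefalcon)

cfgfile <- system.file("extdata", "worked_example.yaml",
                       package = "icefalcon")
res <- run_pipeline(cfgfile)
res$analyses$light_areas_vs_bright_areas
#> ICE FALCON analysis: light_areas <-> bright_areas
#>   forward (light_areas -> bright_areas): beta_self 0.802 -> 0.770,
#>       beta_cotwin 0.513 -> 0.070, rho 0.59
#>     label: combination | Pr = 89%, causal effect = 0.716, confounding = 11%
#>   reverse (bright_areas -> light_areas): beta_self 0.770 -> 0.727,
#>       beta_cotwin 0.404 -> 0.144, rho 0.53
#>     label: combination | Pr = 58%, causal effect = 0.448, confounding = 42%
#>   summary: bidirectional causation (with familial confounding where Pr < 1)
```

Reading the forward direction: conditioning on a woman's own light-areas
score collapses her co-twin's coefficient from 0.513 to 0.070 (an 86%
attenuation) while her own coefficient barely moves (0.802 → 0.770), so
89% of the light–bright association is attributed to causation and 11% to
familial confounding; the reverse assignment is also consistent with
causation, i.e. the two measures influence each other. The single
decomposition is available directly:

```r
decompose(falcon_triplet(0.802, 0.513, 0.770, 0.070), rho = 0.59)
#>   change_self change_cotwin    pr causal_effect confounding_fraction
#>         0.032         0.443 0.893         0.716                0.107
```

`export_graph(res$analyses)` assembles every direction labelled causal
into a weighted diagram (DOT and JSON); `autoplot()` on an analysis shows
the four coefficients with robust intervals.

Simulated studies use the same pipeline end to end:

```r
cfg <- calibrate_pair_config("light_areas", "bright_areas",
  rho_x = 0.59, rho_y = 0.53, r_within = 0.81, r_cross = 0.52,
  n_pairs = 371,
  raw_transforms = mammographic_transforms()[c("light_areas",
                                               "bright_areas")])
pairs  <- simulate_pairs(cfg, seed = 1)
scores <- risk_scores(pairs, c("light_areas", "bright_areas"))
run_pair_analysis(scores, "light_areas", "bright_areas",
                  B = 1000, seed = 1)
```

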
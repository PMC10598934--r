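---
title: "Separating causation from familial confounding in MZ twin pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating causation from familial confounding in MZ twin pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icefalcon)
```

## The question the package answers

Mammogram-based risk scores — the areas of a mammogram that are light,
bright or brightest at increasing pixel-brightness thresholds, and
texture-based scores such as Cirrus — are correlated with each other and
predict breast cancer risk. Are those correlations causal (one aspect of
breast tissue driving another) or do they merely reflect familial factors —
genes and shared environment — that influence several measures at once?

Monozygotic (MZ) twin pairs let the two explanations be separated without
measuring the confounders. A twin's exposure is correlated with her
co-twin's exposure through everything the pair shares; if the exposure
causes the outcome, the co-twin's exposure predicts a woman's outcome *only
through* the woman's own exposure, whereas familial confounding makes the
co-twin's exposure predictive in its own right. ICE FALCON (Inference about
Causation from Examination of FAmilial CONfounding) turns this contrast
into a three-model regression procedure.

## The three models and the decomposition

All analyses use *risk scores*: each raw measure is power-transformed to
approximate normality, adjusted for age at mammography, and standardised
(mean 0, SD 1). For a predictor score $X$ and outcome score $Y$, the data
are *double entered*: each twin appears once as "self" with her co-twin's
values attached, in both orderings, giving two rows per pair. Three
marginal regressions are fitted:

* Model 1: $Y_{self} = \beta_{self} X_{self} + \varepsilon_1$
* Model 2: $Y_{self} = \beta_{co\text{-}twin} X_{co\text{-}twin} + \varepsilon_2$
* Model 3: $Y_{self} = \beta'_{self} X_{self} + \beta'_{co\text{-}twin} X_{co\text{-}twin} + \varepsilon_3$

Under causation, $\beta_{co\text{-}twin} \ne 0$ but conditioning on the
twin's own exposure explains it away: $\beta'_{co\text{-}twin} \approx 0$
while $\beta'_{self} \approx \beta_{self}$. Under familial confounding both
conditional coefficients attenuate to a similar proportional extent. With
$\Delta\beta = \beta - \beta'$ and $\rho$ the within-pair correlation of
the predictor score, path tracing gives the fraction of the Model 1
association attributable to causation:

$$
\Pr \;=\;
\frac{\bigl(\Delta\beta_{co\text{-}twin}
 - (\Delta\beta_{self} / \beta_{self})\,\beta_{co\text{-}twin}\bigr)/\rho}
     {\beta_{self}}
$$

The causal effect size is $\beta_{self} \times \Pr$ and the
familial-confounding fraction is $1 - \Pr$. `decompose()` evaluates this at
full precision, flags (never clamps) values outside $[0,1]$, and refuses to
divide by $\rho = 0$ or $\beta_{self} = 0$.

```{r}
decompose(falcon_triplet(0.802, 0.513, 0.770, 0.070), rho = 0.59)[
  , c("pr", "causal_effect", "confounding_fraction")]
```

## Regression machinery and the working correlation

The outcomes of the two twins in a pair are correlated, so the models are
fitted by generalised estimating equations clustering on pair, with robust
(sandwich) standard errors (`fit_gee()`). One choice here matters more than
it looks: Models 1 and 2 deliberately omit part of the cluster's
covariates (Model 2, for instance, regresses a woman's outcome on her
co-twin's predictor while ignoring her own). If a non-diagonal working
correlation is used in that situation, the estimating equations mix the
omitted within-cluster covariances into the score and the point estimates
no longer converge to the marginal coefficients that the decomposition
formula is written for — under the correlation structure typical of these
scores the Model 2 coefficient can be inflated by tens of standard errors.
The package therefore defaults to the independence working correlation:
point estimates equal ordinary least squares on the double-entered rows
(which *are* the marginal associations), and the within-pair dependence is
handled where it belongs, in the cluster-robust sandwich. An exchangeable
working correlation remains available (`corstr = "exchangeable"`) and is a
correctly specified — and slightly more efficient — choice for Model 3,
which contains both cluster covariates; the exchangeable moment estimate of
the residual pair correlation is always reported as a diagnostic. A
conditional variant that regresses on the co-twin's outcome directly is
available behind `conditional = TRUE` but is not the default.

Significance of the Model 1 → Model 3 coefficient changes is assessed by a
cluster bootstrap (`bootstrap_changes()`): pairs are resampled with
replacement, the three models refitted per replicate, and a two-sided
p-value formed from the normal approximation with the bootstrap standard
error. The default is $B = 1000$ replicates (at least 200 recommended for
reporting); resampling is seeded and reproducible, and degenerate
replicates are dropped and counted, with more than 5% dropped an error.

## Correlation structure

`twin_correlations()` estimates three kinds of Pearson correlation:
within-pair within-trait (double-entered tuples $(v_1, v_2)$ and
$(v_2, v_1)$, the standard twin-study convention, invariant to twin
labelling), within-twin cross-trait (one tuple per woman), and cross-twin
cross-trait (double-entered). Fisher-z 95% intervals use the number of
pairs for pair-level correlations by default — double-entered tuples
duplicate information, and using $2n$ would be anti-conservative — with
the $2n$ convention available via `n_convention = "double"`.

## Score construction

`risk_scores()` implements the preprocessing: a Box–Cox power
transformation fitted by profile likelihood over a grid on $[-2, 3]$ (step
0.05) with golden-section refinement, an optional user-supplied shift for
measures that live far from zero (a Cirrus-like score is normalised by
$(x - 2907)^2$, i.e. shift $-2907$, $\lambda = 2$), ordinary
least-squares adjustment for age at mammography, and standardisation of
the residuals using the $n-1$ sample SD. Known transforms can be forced
verbatim (`mammographic_transform_specs()` supplies the cube root, fifth
root and shifted square used for the four mammographic measures).
Adjustment is run on individuals, ignoring pair clustering: clustering
affects neither the residuals nor their moments, and inference downstream
is cluster-aware. Incomplete pairs are dropped with a reported count.

Pathways not running through a third score are probed by residualising
both analysis scores on that score (`adjust_for` in
`run_pair_analysis()`); because every score is already an age-adjusted
residual, this is exactly the joint adjustment for age and the third score
by the Frisch–Waugh–Lovell theorem. The within-pair predictor correlation
$\rho$ entering the decomposition is always recomputed on the score
version actually analysed — the subtlest reproducibility hazard in the
procedure, and one the pipeline log records explicitly.

## Decision rules

Each direction of an analysis is labelled from the coefficient pattern at
a nominal $\alpha = 0.05$ (no multiple-testing correction, mirroring usual
reporting practice):

* **causation** — $\beta_{co\text{-}twin}$ significant, its conditional
  version significantly closer to zero, self coefficient stable;
* **familial confounding** — both changes significant and proportionally
  similar (within a configurable tolerance, default 0.25, since "similar
  extent" has no canonical numeric criterion);
* **combination** — both changes significant with the self change
  proportionally smaller;
* **no evidence** — $\beta_{co\text{-}twin}$ not significant;
* **inconsistent** — any other pattern, notably conditional coefficients
  moving *away* from zero, which is not consistent with the predictor
  causing the outcome. $\Pr$ is never reported from such a direction.

Both directions are always fitted (`run_pair_analysis()` swaps predictor
and outcome), and the reconciled summary reports causal fractions only
from directions labelled causation or combination.

## The synthetic twin-pair generator

The study data behind analyses of this kind are typically available only
on request, so the package ships a generator (`simulate_pairs()`) whose
population behaviour is known exactly. Each trait is a linear-Gaussian
structural equation: a pair-shared trait-specific factor (SD
`familial_loading`), loadings on pair-shared latent confounders, an
individual-specific shock (SD `unique_sd`), and directed within-person
causal paths between traits. Cross-twin causation is excluded by
construction: a twin's score never acts on her co-twin's scores, so all
cross-twin covariance flows through the shared components. Cyclic path
systems (bidirectional causation) are resolved by the reduced form
$(I - B)^{-1}$, which keeps every moment closed-form; a spectral radius
$\ge 1$ is an error naming the offending paths.

`population_moments()` and `theoretical_coefficients()` evaluate, without
simulation, the exact covariance of
$(X_{self}, X_{co\text{-}twin}, Y_{self}, Y_{co\text{-}twin})$, the three-model
coefficients (covariance ratios and the $2 \times 2$ normal equations) and
the exact decomposition — the oracle every estimation routine is tested
against. Third-score adjustment is mirrored in closed form by partialling
each individual's scores on her own third score.

Defaults emulate screening-age mammographic data: age uniform on 40–70
years at the pair level with a small within-pair jitter (SD 0.5 years,
mammograms being taken on different dates), age slopes sized so age
explains about 2% of the light-areas score variance and 8–11% of the
others, and monotone power maps to the raw scales (cubes for light and
bright areas in cm², a fifth power for the brightest areas, a shifted
square root for a Cirrus-like score) whose inverses are exactly the
printed normalising transforms, so the preprocessing is exercised end to
end. `calibrate_pair_config()` solves in closed form for a two-trait
configuration reproducing any feasible target set of within-pair,
within-twin cross-trait and cross-twin cross-trait correlations; the
shipped `config_light_bright.yaml` and `config_brightest_cirrus.yaml`
match the published correlation structure of the four mammogram scores at
371 pairs. An optional pair-level stratifier emulates percent density
(median 30.5% style splits) for `stratified_analysis()`, which stratifies
at the pair level on the within-pair mean.

What the generator does *not* emulate: measurement error beyond the
additive unique component, dizygotic pairs, non-linear or non-Gaussian
dependence, missingness mechanisms, and the joint dependence of more than
three scores at once (analyses are run one predictor–outcome pair, plus an
optional third score, at a time). Passing tests therefore demonstrate that
the estimation machinery recovers the truth under the linear-Gaussian
shared-factor model — the model under which the decomposition formula is
derived — not that real mammographic data satisfy that model.

## Numerical choices and test problem sizes

Determinism: every stochastic routine takes a seed, and equal seeds give
byte-identical output. Box–Cox fits that land within $10^{-4}$ of zero
return the log exactly. Standardisation uses the $n-1$ SD (the convention
is visible in the code and documented here since either choice is
defensible). The GEE solver declares non-convergence after 50 iterations
with the update trace in the error; the bootstrap warns below $B = 200$.
Sampling checks in the test suite use: 50 000 pairs for oracle-equivalence
and causal-fraction recovery (estimates within ±0.03 of truth across
$\Pr \in \{0, 0.25, 0.5, 0.75, 1\}$), 1000 independent datasets of 500
pairs with $B = 200$ for the null calibration of the bootstrap change
test, and 100 seeds per shipped configuration at the study size of 371
pairs for the correlation-structure emulation. At 371 pairs the sampling
spread of a within-pair correlation (SD ≈ 0.035) exceeds what the
published interval widths (± ≈ 0.05) would suggest, so a minority of
replicates fall outside those intervals even under exact calibration —
the emulation check in the test suite reports exactly this.

## Limitations

The decomposition inherits ICE FALCON's assumptions: linearity on the
score scale, no cross-twin causation, and confounders shared symmetrically
by both twins. $\Pr$ is a ratio of estimated quantities and can leave
$[0,1]$ in small samples or weak associations — it is then flagged rather
than truncated, and conclusions should lean on the labels, not the point
value. The bootstrap change test treats the pair as the exchangeable unit;
with few pairs (< 30 the code warns) the normal approximation for the
change statistics weakens.
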
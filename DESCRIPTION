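Package: icefalcon
Title: Causal Decomposition of Twin-Pair Associations via ICE FALCON
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating causation from familial confounding in
    monozygotic twin-pair data using the ICE FALCON three-model regression
    procedure (Inference about Causation from Examination of FAmilial
    CONfounding). Includes construction of normalised, age-adjusted risk
    scores from skewed raw measures via Box-Cox power transformation,
    twin-pair correlation structure with double entry, Gaussian generalised
    estimating equations with exchangeable working correlation and robust
    standard errors, a cluster bootstrap for coefficient-change tests, the
    path-tracing decomposition of each association into causal and
    familially confounded fractions, and a linear structural twin-pair
    simulator with exact closed-form population moments for every quantity
    the procedure estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    nlme,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
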
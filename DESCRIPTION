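Package: growthpf
Title: Adaptive Particle-Filter Inference of Gompertz and Logistic
    Growth Models for Shake-Flask Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Online, adaptive estimation of time-varying Gompertz and
    Logistic growth-model parameters from shake-flask biomass
    (back-scatter) and dissolved-oxygen sensor time series using a
    sequential-importance-resampling particle filter with hierarchically
    adapted, per-parameter state-noise precisions. Includes static-model
    fitting by reshuffled-profile MCMC, forecasting of future signal
    values, prediction of harvest and critical-oxygen event times,
    Savitzky-Golay post hoc event estimation, paired sign-flip
    permutation testing with Benjamini-Hochberg FDR control, a
    synthetic-culture generator with regime switches and step events,
    and an unbiased split-wise evaluation protocol.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    zoo
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
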
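# growthpf

Adaptive, online inference of Gompertz and Logistic growth-model
parameters from shake-flask sensor signals, with forecasting of future
biomass (BM) and dissolved-oxygen (DO) levels and advance prediction of
operational events: the optimal harvest time (95% of maximal biomass) and
critically low oxygen (20% of the initial DO level).

## Who this is for

Scientists doing early-stage bioprocess development — strain
characterization and substrate optimization in online-monitored shake
flasks — where no historical data exist for the condition being tested and
growth dynamics can change mid-culture (nutrient limitation, sensor
steps). A statically fitted growth model cannot be built without prior
replicates and cannot react to change; `growthpf` fits the model *while
the culture runs*.

## The method

Signals are rescaled (BM/1000, DO/10) and log transformed. On that scale
growth follows one of

- Gompertz: `y(t) = k · exp(−exp(b − c·t))`
- Logistic: `y(t) = k / (1 + exp(b − c·t))`

with asymptote `k`, offset `b`, and rate `c` (per hour); flipping the
signs of `b` and `c` mirrors the curve for declining DO. A
sequential-importance-resampling particle filter carries an ensemble of
`(k, b, c)` triples through the data, weighting each particle by the
Gaussian likelihood of the last `W = 20` measurements and resampling at
every step. Its distinguishing feature is a hierarchical layer that
re-estimates the state-noise precisions `Λ, ν, γ` of the three parameters
from the recent coherent motion of the ensemble (conjugate Gamma updates
for `Λ, ν`; a Metropolis–Hastings step for `γ`), so the filter switches
automatically between near-static precision under stationary growth and
fast tracking after a change. Static reference models are fitted with the
same kernel run over reshuffled profiles; PF-vs-static comparisons use
paired sign-flip permutation tests with Benjamini–Hochberg FDR control.

See the methods vignette
(`vignettes/adaptive-growth-filtering.Rmd`) for the full model, defaults
and design rationale.

## Worked example

Seed the filter with a static fit of a similar culture, then monitor a new
culture that suffers a +0.3 log-unit sensor step at 4 h:

```r
library(growthpf)

repl <- simulate_culture(tibble::tibble(start_time = 0, k = 1.5, b = 3, c = 1),
                         noise_sd = 0.05, duration = 8,
                         mean_interval = 0.0667, seed = 77)
init <- fit_static(repl[, c("time_h", "value")], "gompertz", seed = 5)

cult <- simulate_culture(tibble::tibble(start_time = 0, k = 1.5, b = 3, c = 1),
                         step_events = tibble::tibble(time = 4, offset = 0.3),
                         noise_sd = 0.05, duration = 8,
                         mean_interval = 0.0667, seed = 11)
pf <- pf_filter(cult[, c("time_h", "value")], "gompertz",
                init = tidy(init, ensemble = TRUE), seed = 42)
pf
#> Particle-filter growth model (gompertz)
#>   updates: 123  particles: 1000
#>   k = 1.819 (sd 0.0123), b = 3.044 (sd 0.109), c = 1.004 (sd 0.0354)
#>   obs noise sd = 0.0584; state-noise sd (k, b, c) = 0.0145, 0.0142, 0.00792
```

The asymptote has absorbed the step (`k ≈ 1.82 ≈ 1.5 + 0.3` on the
plateau) while `b` and `c` stay at the culture's true transition dynamics;
the inferred observation noise matches the simulated 0.05. Event and
signal forecasts come straight off the ensemble:

```r
predict_event(pf, event_spec("BM"))
#>   tpred tpred_sd noncrossing channel fraction     reference
#> 1 5.994    0.181           0      BM     0.95 max_of_signal

predict(pf, c(8.5, 9, 10))
#>   time_h .pred .lower .upper
#> 1    8.5 1.812  1.792  1.830
#> 2    9.0 1.815  1.795  1.833
#> 3   10.0 1.818  1.798  1.837
```

`autoplot(pf)` draws the Fig.-4-style diagnostic (signal, rolling
one-step mse, state-noise sds); `run_protocol()` executes the full
unbiased PF-vs-static evaluation across 30–80% splits and
`protocol_table()` formats it as the familiar report layout. A thin
command-line front end is installed at `exec/growthpf`
(`growthpf simulate | fit-static | filter | events | evaluate | protocol`).

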
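---
title: "Adaptive particle-filter inference of growth models for shake-flask monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive particle-filter inference of growth models for shake-flask monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(growthpf)
```

## The problem

Shake flasks are the workhorse of early-stage bioprocess development:
cheap, parallel, and increasingly monitored online through optical
back-scatter (biomass, BM, in Attenuation Units) and fluorescence-quenching
oxygen sensors (dissolved oxygen, DO, in percent of maximum). What online
monitoring alone does not give is *foresight*: when will the culture reach
95% of its final biomass (the operational harvest point), and when will
oxygen fall below 20% of its initial level? Worse, cultures probing novel
strains or substrates routinely violate stationarity — growth slows when a
nutrient runs out, or the optical response jumps mid-run — so a model fitted
once and frozen will mispredict exactly when prediction matters most.

`growthpf` addresses this with a sequential-importance-resampling particle
filter whose particles are parameter triples of a three-parameter growth
law, and whose *state-noise levels are themselves inferred online*, so the
filter moves automatically between two modes: near-static precision while
growth is stationary, and fast tracking when the dynamics change.

## Models and conventions

Signals are modelled on a transformed scale: BM is divided by 1000, DO by
10, and both are log transformed (`transform_signal()`); sigmoidal growth
laws fit these log-scale signals markedly better than the raw ones. Two
families are supported,

$$y(t) = k\,e^{-e^{b - c t}} \quad \text{(Gompertz)}, \qquad
  y(t) = \frac{k}{1 + e^{b - c t}} \quad \text{(Logistic)},$$

with asymptote $k$ (log-units), offset $b$ (dimensionless) and rate $c$
(per hour). Monotone growth has $b > 0,\ c > 0$; flipping both signs
mirrors the curve in time, which is how declining DO is represented. The
mirror axis is $t = b/c$ (the algebraic consequence of the
parameterization: substituting $(-b, -c)$ and $t \mapsto 2b/c - t$ leaves
the exponent unchanged). Event predictions invert the curve in closed form
(`crossing_time()`); the inverse exists for any target fraction in
$(0, 1)$ of the asymptote whenever $c \neq 0$.

$k$ is deliberately unconstrained in sign: a log-scale asymptote near or
below zero is legitimate. Validity checks (`growth_direction()`) warn
about mixed-sign $(b, c)$ rather than rejecting them.

## The filter

The filter state is an ensemble of $N$ particles (default 1000), each a
$(k, b, c)$ triple. One update step (`pf_update()`):

1. append the new measurement to a sliding window of the last $W = 20$
   points — the window defines the likelihood, so the filter is local in
   time by construction;
2. propagate every particle by independent Gaussian random-walk increments
   with per-parameter variances $1/\Lambda$, $1/\nu$, $1/\gamma$;
3. weight each particle by the Gaussian likelihood of *all* windowed
   values given its curve (log-space, max-shifted, so weight collapse
   degrades gracefully instead of producing `NaN`);
4. resample (systematic by default; multinomial available), resetting the
   weights to $1/N$;
5. update the observation-noise and state-noise precisions (below).

Default window sizes ($W = 20$ samples, state-noise window $S = 10$
update steps) and the Gamma hyperpriors $(0.1, 1)$ for all precisions,
with Metropolis–Hastings proposal width $\delta = 0.9$, are the
configuration the method was calibrated with; all are exposed in
`pf_init()`.

### Observation noise

A single precision $\tau$ is shared by the ensemble and updated by a
discounted conjugate rule driven by the one-step-ahead innovation $e_t$
(the difference between the new measurement and the ensemble forecast of
it, computed *before* the update):
$a \leftarrow \rho a + \tfrac12$, $b \leftarrow \rho b + \tfrac12 e_t^2$,
$\tau = a/b$, with $\rho = 1 - 1/W$. In steady state $\tau$ approaches the
reciprocal mean squared innovation over roughly one window. This choice is
deliberate: it makes the likelihood sharp while tracking is good (tight
posteriors, fast convergence of $b$ and $c$) and flat during adaptation
(so the filter explores rather than over-commits), and it forgets the
initial misfit phase. An undiscounted windowed per-particle update was
tried first and rejected: with the non-informative prior and only $W$
residuals the inferred noise is floored near $\mathrm{sd} \approx 0.3$
regardless of the data, leaving the likelihood too flat to finish
converging the transition parameters.

### State noise

Each parameter has its own precision ($\Lambda$ for $k$, $\nu$ for $b$,
$\gamma$ for $c$). Their sufficient statistic per update step is the
*coherent motion of the ensemble*: the squared change of the weighted
ensemble mean, counted once per particle. The last $S = 10$ such entries
give the conjugate Gamma posterior (shape $g + NS/2$, rate
$h + \tfrac12\sum$), whose mean is assigned to $\Lambda$ and $\nu$;
$\gamma$ instead takes one Metropolis–Hastings step against the same
posterior density, with a multiplicative uniform proposal
$\gamma' = \gamma u$, $u \sim U(\delta, 1/\delta)$ and Hastings correction
$\gamma/\gamma'$ (`mh_gamma_step()` — its long-run behaviour against an
analytic Gamma target is verified in the test suite).

Why the ensemble-mean motion and not the raw per-particle increments?
Because demanded parameter motion manifests as *selection across the
ensemble spread*, not as selection on the per-step innovations: at a level
step the ensemble mean of $k$ travels far while each particle's own
innovation stays near its prior scale. Feeding the raw innovations back
into the precisions both under-detects change and, absent selection
pressure, turns the update into a self-confirming random walk. The
coherent-motion statistic detects a $+0.3$ log-unit step with a three- to
five-fold rise of the $k$ state-noise sd within ten updates — the largest
relative rise of the three parameters, matching the intuition that a level
step is best absorbed by the asymptote — and decays back once one-step
errors normalise, as the window flushes.

Initial precisions are set so the random-walk sd starts at a tenth of the
seed ensemble's spread in each parameter: small enough not to destroy an
informative initialization, large enough that the hierarchical update
takes over within a few steps. (Starting at the Gamma-prior mean
precision of 0.1 — random-walk sd above 3 — scatters any informative
ensemble on the first update and was rejected.)

## Static fits and initialization

A static (time-invariant) model is fitted with the *same* update kernel
run over randomly reshuffled `(time, value)` pairs (`fit_static()`): with
the profile reshuffled, the sliding window always spans the dynamics of
the whole culture, so the ensemble targets a single parameter set. Sweeps
re-permute the data; fitting stops early when every posterior mean moves
by less than `tol = 1e-3` between sweeps (default cap 50 sweeps, typically
4–10 suffice). On noiseless data the posterior means agree with a
Levenberg–Marquardt least-squares fit to a fraction of a percent (tested
at 2%).

Cold starts draw particles uniformly from ranges bracketing the observed
signal range and time span, with $b$ coupled to a transition-midpoint
draw ($b = c\,t_{\text{mid}}$) so every initial curve crosses the
observed window. In routine use the filter is instead seeded with the
ensemble of a static fit of a *similar* culture — initialization profiles
should resemble the monitored culture, and all evaluation here follows
that workflow.

## Events

- Post hoc reference times (`posthoc_event_time()`): the completed signal
  is smoothed with a Savitzky–Golay filter (order 6, window 21, mirrored
  ends) and the reference time is the sample where the smoothed signal is
  closest to the target fraction of its reference level — maximum of the
  smoothed signal for BM (harvest, 95%), first smoothed value for DO
  (critical oxygen, 20%; for a declining curve the initial value is also
  its maximum, and both references are selectable in `event_spec()`).
  Argmin ties break toward the earliest time; a series that never reaches
  the target returns the boundary time with a `noncrossing` flag.
  The mirrored end windows mean polynomial invariance of the smoother
  holds in the interior but not at the edges — event times near the very
  ends of a profile inherit that distortion.
- Forecast times (`predict_event()`): each particle's curve is inverted in
  closed form at the fraction of its *own* reference (its own asymptote
  for BM — forward-looking, independent of how far the signal has come);
  the prediction is the weighted mean of finite crossings, with the
  non-crossing fraction reported and no number fabricated when nothing
  crosses.
- `event_error()` is the signed difference `tpred - topt` in hours;
  `event_loss()` is the relative difference of the smoothed signal at the
  two times, in percent.

## Evaluation machinery

Predictions are scored only on strictly-future samples; once a point has
updated the filter it never enters an error again. `mse()` divides the
squared-error sum by the number of future points so values stay comparable
as the filter advances. PF–SM comparisons use a one-sided paired sign-flip
permutation test (`paired_permutation_test()`): the per-time statistic is
the difference of squared residuals, the null distribution is built by
random sign flips (default $K = 10^5$), and the p-value is the fraction of
flip replicates whose mean falls strictly below the observed mean — ties
are not counted, which is immaterial for continuous residuals; a zero
p-value is reported as $< 1/K$. Exhaustive enumeration replaces sampling
for $n \le 20$. Across splits, p-values map to Benjamini–Hochberg FDRs
(significance at FDR < 0.05); `log(mse)` columns use the natural
logarithm. The tracking diagnostic is a rolling mean of squared
one-step-ahead errors over 15 samples (`rolling_mse()`), with
partial-window values flagged.

The evaluation protocol (`run_protocol()`) mirrors unbiased practice: the
static competitor is fitted to a *different* replicate culture, the filter
is initialized on further independent cultures, and reports are produced
at split fractions 30–80% for BM and 30–60% for DO — the late DO tail sits
at effectively zero oxygen, and learning to predict zeros is not
informative. Split boundaries land on sample indices by
`floor(fraction * N)`. The filter runs continuously across splits
(snapshots are taken at split indices); restarting per split would discard
the online character being evaluated.

## The synthetic-data generator

`simulate_culture()` produces the study conditions every test runs on:
a Gompertz or Logistic backbone on the transformed scale, additive
Gaussian noise, irregular sampling (each interval jittered uniformly by a
fraction of the mean interval, default 0.15), parameter-regime switches
(discontinuous by default; a `continuous` mode re-solves $b$ at each
switch to emulate growth slowdowns), and additive step events emulating
sensor-response jumps. `simulate_do_profile()` applies the declining sign
convention with an optional floor for the near-zero oxygen tail.

Default study conditions, chosen once: asymptote $k = 1.5$, offset
$b = 3$, rate $c = 1\,\mathrm{h}^{-1}$ (transition midpoint 3 h, harvest
crossing just before 6 h), noise sd 0.05 log-units, roughly 120 samples.
Growth-phase studies observe 8 h (monitoring ends shortly after harvest);
event studies observe 12 h so the signal genuinely plateaus, which is what
makes "95% of the maximum" and "95% of the asymptote" coincide. These
magnitudes match log-scale back-scatter profiles of *E. coli* shake-flask
cultures; what the generator does *not* emulate are sensor artefacts
beyond level steps, autocorrelated noise, or any mechanistic
oxygen-transfer dynamics — passing tests demonstrate correct inference
under the stated phenomenology, not robustness to every failure mode of
real optics.

## Numerical choices and degenerate inputs

- All likelihood work is in log space with max-shift; a fully underflowed
  weight vector falls back to uniform rather than propagating `NaN`.
- Precisions are floored at $10^{-12}$; `crossing_time()` refuses
  $c = 0$ and fractions outside $(0, 1)$; event predictions exclude
  non-crossing particles instead of averaging infinities.
- Weighted quantiles use the inverse-CDF convention on sorted particles.
- Determinism: every stochastic entry point takes a `seed`; a fixed seed
  reproduces particle trajectories bit for bit.

## Worked example

```{r example, eval = FALSE}
library(growthpf)

# a replicate-condition culture seeds the filter
repl <- simulate_culture(tibble::tibble(start_time = 0, k = 1.5, b = 3,
                                        c = 1),
                         noise_sd = 0.05, duration = 8,
                         mean_interval = 0.0667, seed = 77)
init <- fit_static(repl[, c("time_h", "value")], "gompertz", seed = 5)

# monitor a new culture with a sensor step at 4 h
cult <- simulate_culture(tibble::tibble(start_time = 0, k = 1.5, b = 3,
                                        c = 1),
                         step_events = tibble::tibble(time = 4,
                                                      offset = 0.3),
                         noise_sd = 0.05, duration = 8,
                         mean_interval = 0.0667, seed = 11)
pf <- pf_filter(cult[, c("time_h", "value")], "gompertz",
                init = tidy(init, ensemble = TRUE), seed = 42)
autoplot(pf)          # signal, rolling mse, state-noise sds
glance(pf)
predict_event(pf, event_spec("BM"))
```

## Known limitations

- The filter is local by design: once the informative transition has left
  the sliding window, $b$ and $c$ are constrained only through the local
  curve shape, and on long plateaus they can drift along the likelihood
  ridge that preserves the windowed fit. Forecasts and event times are
  robust to this (the ridge preserves the local curve); the raw parameter
  values late in a plateau are not individually interpretable.
- Cold starts on profiles whose early phase is flat leave $b$
  under-determined until the transition arrives; initialize from a static
  fit of a similar culture when one exists.
- BM and DO channels are filtered independently; joint multi-signal
  filtering is out of scope, as are growth laws beyond Gompertz/Logistic.
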
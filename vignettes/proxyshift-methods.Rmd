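---
title: "Methods: uncertainty-aware multi-proxy reconstruction with proxyshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-aware multi-proxy reconstruction with proxyshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxyshift)
```

## The problem

Sediment-core proxy records are doubly uncertain: every measurement carries
analytical error, and every depth carries dating error that grows downcore.
Any synthesis of several proxies — and any claim that a proxy changed
significantly at some age — must carry both error sources through to the end
result. `proxyshift` implements that propagation for the kind of
late-Holocene polynya reconstruction it was built around: a marine core whose
diatom and *Chaetoceros* resting-spore fluxes track primary production and
whose IP25/HBI III biomarkers track sea-ice state, and a lake core whose
Cd:Ti, δ¹⁵N, sterol and diatom-assemblage indices track the marine-derived
nutrient input of an adjacent little auk colony.

The pipeline has five stages, each usable on its own:

1. **Proxy calculation** — fluxes from concentrations and mass accumulation
   rates, TOC normalisation, the cholesterol/(cholesterol+β-sitosterol)
   index, fractional sterol, binned Cd:Ti count ratios, relative abundances
   and an assemblage PCA index.
2. **Chronology** — an ensemble of monotone age-depth realisations from
   dated horizons.
3. **Monte Carlo propagation** — per-proxy probability densities, median
   series and 90% envelopes on a common time grid.
4. **PC synthesis** — PCA of the median series with an uncertainty envelope
   propagated onto PC1.
5. **Trend-change detection** — penalized-spline trends with CAR(1)
   residuals and first-derivative confidence intervals.

A synthetic-record generator with known truth closes the loop: every stage
is validated against records whose age model, signal histories and injected
change points are known exactly.

## Chronology: a surrogate ensemble sampler

Full Bayesian accumulation modelling (as in BACON) calibrates radiocarbon
dates against a calibration curve under accumulation-rate priors. The
downstream consumer here needs only one property of such a model: a
depth-dependent distribution of plausible ages. `sample_age_models()`
therefore uses a deliberately simple surrogate, and is documented loudly as
such:

* each draw perturbs every dated horizon by Gaussian noise at its 1σ
  magnitude (stated uncertainties are divided by their stating convention —
  2σ for the marine record, 3σ for the lake record — before sampling);
* monotonicity is restored by isotonic least-squares projection
  (pool-adjacent-violators via `stats::isoreg`) rather than rejection
  sampling, whose acceptance probability collapses when errors are large
  relative to horizon spacing;
* ties created by the projection are broken by a cumulative epsilon
  (10⁻⁹ of the record's age span) so every draw is strictly increasing; the
  epsilon is applied only where ties exist, so error-free chronologies pass
  through bit-exactly;
* draws are evaluated on the requested depth grid by piecewise-linear
  interpolation. Extrapolation beyond the outermost dates is refused by
  default and available as constant-rate extension behind a flag.

Because the perturbation and the unknown truth share the same Gaussian
error model, the ensemble's 5th–95th percentile band covers the true
chronology at very close to its nominal 90% — a property the test suite
verifies over 200 synthetic replicates. Gaussian errors are an assumption:
calibration-curve multimodality, if present in real stated uncertainties,
is not reproduced.

`apply_reservoir_offset()` implements the marine reservoir correction as a
simple age shift with quadrature-combined uncertainty (default 140 ± 60
years, the value appropriate for deep sites under the West Greenland
Current).

## Monte Carlo propagation

`simulate_ensemble()` pairs age-model draw *i* with measurement-noise
realisation *i* — the simplest joint propagation of the two error sources.
Relative noise perturbs multiplicatively, `v·(1 + ε)`; absolute noise
additively, `v + ε`; both with `ε ~ N(0, σ)`. Each perturbed (age, value)
path is linearly interpolated onto the common time grid, and the draws are
summarised by their median, their 5th/95th percentiles, and a 2D frequency
histogram (time × 50 equal-width value bins).

Numerical choices worth knowing:

* **Time grid.** Default 20-year steps over the *intersection* of all
  draws' age spans. Restricting to the intersection makes the
  draw-conservation invariant exact — every histogram column sums to
  `n_draws` — at the cost of trimming a few decades at the record ends.
  User-supplied grid points outside the intersection are dropped with a
  message.
* **Quantiles** use R's default (type 7) interpolation; the fraction of
  draws inside the envelope is 90% up to interpolation and ties, which the
  acceptance checks confirm to within one percentage point at 10,000 draws.
* **Determinism.** All randomness flows from one integer seed through a
  scoped generator that restores the caller's RNG state; identical seeds
  give bit-identical ensembles.

The preset noise magnitudes are the study conditions the generator
emulates: ±7.5% (relative, 1σ) for the three marine series, and 2%
(Cd:Ti), 0.5‰ (δ¹⁵N), 0.001 mg cm⁻² yr⁻¹ (fractional sterol) and 10%
(diatom index) for the lake series, with dated-horizon uncertainties stated
at 2σ (marine) and 3σ (lake).

## PC synthesis and envelope propagation

`pca_median()` z-scores each median series over time and eigendecomposes
the correlation matrix — equivalent to PCA on standardised variables, so
rescaling any raw series leaves loadings unchanged. Components are ordered
by decreasing eigenvalue and the sign is fixed so a chosen orientation
proxy (diatom flux for the marine record, δ¹⁵N for the lake) loads
positively; only PC1 is interpreted downstream.

"Propagating the Monte Carlo envelopes as fractional mean uncertainties"
onto PC1 is not a uniquely defined operation, so the package declares one
convention and isolates it in `propagate_pc_envelope()` where alternates
can be swapped:

* per proxy, the fractional mean uncertainty is the time-mean of
  `(p95 − p5) / (2·|median|)`;
* where `|median|` falls below 5% of its own time-mean, the denominator is
  floored there so near-zero crossings do not dominate the mean (if a
  median is identically zero the absolute half-width is used instead);
* the PC1 envelope half-width at each time is `|PC1|` times the
  loading-weighted mean `Σ|lᵢ|·fᵢ / Σ|lᵢ|`.

This yields the vertical (magnitude) envelope. The horizontal (time)
envelope is reported separately when an age ensemble is supplied, by
mapping each grid time through the ensemble's 5th/95th-percentile age-depth
relations.

## Trend-change detection

`fit_trend()` models a series as a cubic penalized regression spline
(default basis dimension 20, appropriate for records of ~80–300 samples;
shrunk with a warning on shorter series). Smoothness is selected by REML by
default; GCV is available per series for cases where REML over-smooths —
that judgement is left to the user, since no automatic criterion is
imposed. With `car1 = TRUE` (REML only) the residuals follow a
continuous-time AR(1) process fitted via `mgcv::gamm` with `nlme::corCAR1`,
which handles the uneven time spacing of sediment records.

Uncertainty comes from draws of the Gaussian approximation to the
coefficient posterior at the fit. Twenty draws mirror a display-oriented
convention but give unstable quantiles, so confidence intervals default to
1,000 draws; the pipeline's `paper_faithful` switch restores 20.
`derivative_ci()` differentiates each draw by central finite differences on
the evaluation grid (one-sided at the endpoints), forms pointwise quantile
intervals (simultaneous intervals are not implemented), and declares a
significant change wherever the interval excludes zero; contiguous flagged
points become non-overlapping, time-ordered intervals whose sign follows
increasing calendar time. `changepoints()` reduces each interval to its
midpoint.

Pointwise 95% intervals examined over ~200 grid points are not a 5%
family-wise test; on pure white noise the suite requires at most a 10%
rate of spurious intervals across replicates, a bound chosen wider than
nominal to absorb the posterior-approximation error. One caveat observed
in practice: when the input series is itself an ensemble median, it is
already very smooth, and wiggle-level features can reach significance; the
CAR(1) term absorbs much but not all of this. Change ages should therefore
be read jointly with the dating envelope, as the recovery tests do.

## The synthetic generator: what it does and does not emulate

`marine_preset()` spans 4,000 years over 540 cm with 11 dated horizons;
`lake_preset()` spans 6,000 years over 177 cm with 10 horizons and 77
proxy samples — the shapes of the cores the package was built around. Both
use linear true age-depth maps, 1σ dating uncertainties growing linearly
downcore (10 → ~110 yr marine, 15 → ~135 yr lake, chosen as typical
late-Holocene radiocarbon magnitudes), and step signals at 2200 yrs b2k
(marine productivity drop, with HBI III rising as production falls) and
4300 yrs b2k (lake: colony arrival lifts all four indicators). The signal
library is restricted to constant, ramp, step and logistic shapes — enough
to emulate abrupt transitions and gradual declines, but a stand-in: the
true functional form of any real proxy history is unknown, and nothing
here simulates radiocarbon physics, calibration wiggles, bioturbation or
sediment mixing. Passing recovery tests on these records therefore
demonstrates correctness of the propagation machinery, not realism of any
particular reconstruction.

The diatom index's "10% uncertainty" is implemented as relative noise, and
the preset keeps the synthetic index strictly positive so relative noise
is well-defined.

## Problem sizes and defaults

Production runs use 10,000 Monte Carlo draws (both the ensemble stage and
the chronology), a 20-year time grid, and 1,000 posterior draws for
derivative intervals. The validation suite scales down where sampling error
allows: coverage properties are checked at 200 replicates × 200 draws,
recovery and false-positive rates at 100 replicates × 100 draws with 400
posterior draws, and the envelope-coverage identity at the full 10,000
draws. These sizes were chosen so each property's sampling noise is well
inside its acceptance band.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config("lake", seed = 1, n_draws = 10000, out_dir = "lake_run")
res <- run_pipeline(cfg)
res$synthesis           # loadings, variance fractions
changepoints(res$trends$pc1$change)
```

The run directory then contains `agemodel.csv`, per-proxy
`ensemble_*.csv`/`density_*.csv`, `pca.csv`, per-series `trend_*.csv`,
`changepoints.csv`, and a `manifest.yml` from which the run is exactly
reproducible.

## Known limitations

* The chronology sampler is a surrogate, not an accumulation model: it
  carries no rate priors and cannot reproduce calibration multimodality.
* The PC1 envelope formula is a declared convention (see above), not an
  estimate of the PC sampling distribution.
* Derivative intervals are pointwise; simultaneous coverage is weaker.
* Below-detection biomarker values are treated as exact zeros.
* Only Gaussian responses and univariate smooths are supported in the
  trend stage.
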
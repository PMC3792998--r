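---
title: "Switching state-space analysis of whale satellite tracks: models and methods"
author: "whaletrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching state-space analysis of whale satellite tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Argos satellite tags on large whales deliver position fixes at irregular
intervals, with errors that range from a few hundred metres (location
class 3) to tens of kilometres (class B) and are distinctly heavy-tailed.
Underneath that noise, migrating baleen whales alternate between two broad
movement modes: directed *transiting* (near-zero turn angles, strong
persistence in speed and direction) and *area-restricted search* (ARS;
slow, tortuous movement with frequent reversals, the classic proxy for
foraging). whaletrack estimates the latent path and the behavioural mode
jointly, then derives the ecological quantities that matter for a
stopover-style analysis: when each animal left the study area, how long it
stayed, where it searched, and whether its activity follows the day-night
cycle.

## Process and observation model

Locations are modelled on a regular grid with time step `dt` (2 h for the
fin-whale configuration, 4 h for blue whales, matching the bulk of the
inter-fix intervals each preset emulates). Writing `d_t = x_t - x_{t-1}`
for the displacement between consecutive latent locations (in degrees
longitude/latitude), the process model is a first-difference correlated
random walk whose parameters switch with the behavioural state `b_t`:

    d_t = gamma[b_t] * T(theta[b_t]) %*% d_{t-1} + e_t,   e_t ~ N2(0, Sigma)

`T(theta)` is the rotation matrix through the mean turn angle `theta`,
`gamma` in [0, 1] is the move persistence (joint autocorrelation of speed
and direction), and `Sigma` is the process covariance shared by both
states (only `theta` and `gamma` switch). Behaviour follows a first-order
Markov chain on {1 = transiting, 2 = ARS} with switching probabilities
`alpha = (P(1|1), P(1|2))`.

Each Argos fix falls inside a grid interval with fractional position
`j` in [0, 1) and is compared with the linear interpolation
`(1-j) x_t + j x_{t+1}`. Longitude and latitude residuals get independent
scaled Student-t densities whose degrees of freedom and scale depend on
the fix's location class; the six-class table ships as editable YAML
(`inst/extdata/argos_error_model.yaml`) with scales growing from class 3
to class B and heavier tails for the poorer classes.

The model is hierarchical in the simplest useful sense: movement
parameters (`theta`, `gamma`, `alpha`, `Sigma`) are shared by all animals
of a species, while the latent path and behaviour sequence are
per-animal. Short tracks therefore borrow strength from long ones.

### Priors

The prior structure inherited from the source model family is made fully explicit here:
`theta[1] ~ U(-pi/4, pi/4)` (transiting turns near zero),
`theta[2] ~ U(-pi, pi)`, `gamma[1] ~ Beta(2, 1)`,
`gamma[2] ~ Beta(1, 2)` with the ordering `gamma[1] > gamma[2]` enforced
by rejection (transiting is, by definition, the more persistent state —
this also pins the state labels), `alpha_i ~ Beta(1, 1)`, half-normal
(scale 0.1 degrees) priors on the process standard deviations and
`U(-1, 1)` on the process correlation.

### Sampler

`fit_hssm()` runs a Metropolis-within-Gibbs sampler written in C++:

* behaviour states are updated by exact discrete Gibbs sweeps given their
  Markov-blanket (previous and next state, and the displacement density);
* switching probabilities have conjugate Beta updates given the
  transition counts pooled across animals;
* latent locations get single-site random-walk Metropolis moves with
  per-state adaptive scales (adaptation runs during burn-in only). With
  probability 0.3 an interior state instead proposes its reflection
  through the midpoint of its neighbours — a symmetric involution that
  flips the local "zigzag parity" of the path. Without this move the
  sampler can dwell for thousands of iterations in a configuration where
  the path chases observation noise and the ARS persistence compensates;
  with it the pair mixes in a few hundred iterations;
* movement parameters get random-walk Metropolis updates with adaptive
  scales; the ARS turn angle is proposed on the circle (wrapped), since
  its posterior often straddles ±pi where reversal behaviour lives.

Each recorded iteration performs two full behaviour/location sweeps and
five parameter-update rounds; "iteration" in the MCMC settings counts
these composite scans. The default protocol is the study protocol: two
chains of 50 000 iterations, 45 000 burn-in, thinning by 5 (2 000 retained
samples); chains start from overdispersed prior draws and from a lightly
smoothed interpolation of the fixes. Fits are reproducible given the seed.
Convergence is summarised by `gelman_rubin()` (potential scale reduction
factor from between/within-chain variances; identical chains report
exactly 1).

### Classification

The behavioural index `b` at a grid time is the mean of the retained
behaviour samples, so it lives in [1, 2]. Following the established
cut-offs, `b < 1.25` is transiting, `b > 1.75` ARS, anything between
uncertain. Locations are summarised by posterior medians with central 95%
credible intervals; speeds are computed between consecutive posterior
medians (medians rather than means, for robustness against the skewed
location posteriors heavy-tailed errors produce).

## Derived analyses

**Kinematics.** Distances are haversine great circles on a sphere of
radius 6371 km; headings are forward azimuths; turn angles are wrapped
differences of successive azimuths, counterclockwise positive, with a
full reversal mapping to +pi and zero-length displacements yielding NA
rather than 0.

**Departure and residency.** Departure from the study area is the start
of the first run of consecutive intervals totalling at least 48 h in
which every interval speed strictly exceeds the pooled median ARS speed.
Animals whose tags stop first are right-censored at track end. Residence
times feed a Kaplan-Meier estimator (via the survival package) and a
weighted binomial-logit regression of the daily departure proportion on
days since tagging, whose 50% point is the headline "half the whales have
left" statistic. Quartiles are read off the survival curve as the
smallest time at which it reaches the level.

**ARS areas.** A discrete ARS area is a maximal run of three or more
consecutive ARS-classified positions; an uncertain position breaks a run.
Each area is measured by the minimum convex polygon of its positions,
computed after a Lambert azimuthal equal-area projection centred on the
area's centroid, so sizes are comparable across latitudes. Collinear
degenerate sets report zero area with a flag.

**Diel profiles.** Sunrise, sunset and solar noon come from the NOAA
solar position algorithm (fractional year, equation of time, declination,
hour angle at zenith 90.833 degrees), including a flag for nights in
which the sun never drops 12 degrees below the horizon (no nautical
darkness, relevant at the northern end of the migration). Hour-of-day
effects are fitted as cyclic harmonic regressions — sine/cosine pairs of
the 24 h cycle, two harmonics by default — rather than spline smoothers:
the fitted curves are periodic by construction, fully transparent, and
sufficient to compare peak timing and flatness between regions. ARS
occurrence uses the same harmonics inside a binomial-logit GLM. Hours are
solar-local (UTC + longitude/15), since the tracks span seventy degrees
of longitude. Per-animal random effects are deliberately not modelled;
pooled and per-animal profiles can be compared instead. The turn-angle
homogeneity question is answered by a seeded permutation test on the
excess of per-group resultant lengths over the pooled resultant length.

## The synthetic population

Because the original telemetry is not public, the package ships a
generator that plays the role of the study data. `simulate_tracks()` runs
the exact process model above (so the fitted model is correctly
specified with respect to it), starting at the Azores tagging grounds
(38 N, 28 W); `observe_tracks()` thins time with a homogeneous Poisson
process, assigns location classes from a configurable frequency table
weighted toward the poor classes (A and B together ~55%, as is typical
for whale deployments), and adds scaled-t noise per class.

Defaults are chosen once to echo the study's regimes and are stated here
as the package's simulation conditions: 8 animals for 30 days at dt = 2 h
in the generic/fin configuration (preset `fin_2009_2012`; the
`blue_2009_2011` preset uses 3 animals, 45 days, dt = 4 h, 7 fixes/day);
12 fixes/day; true parameters `gamma = (0.9, 0.3)`, `theta = (0, pi)`,
`alpha = (0.95, 0.1)` (mean dwell times of roughly 40 h transiting and
20 h ARS), process SD 0.025 degrees per coordinate, initial displacement
0.1 degrees per step (about 5.5 km/h, a realistic cruising speed). The
behaviour chain starts in transiting. These are well-separated regimes:
they test that the machinery recovers a clearly two-state population, not
that the method would resolve subtler real-world mixtures.

What the generator does *not* emulate: duty-cycled transmission caps,
tag failure as anything but a hard track end, environment-driven
switching (prey, bathymetry), and antimeridian crossings (the state space
is planar degrees, appropriate for the mid-Atlantic study region).
Passing recovery tests on this population therefore demonstrates
correctness of the implementation, not field performance on arbitrary
data.

## Numerical choices and conventions

* Grid mapping: `time = t0 + (t - 1 + j) * dt` with `j` in [0, 1);
  reconstruction is exact to well under a second.
* Duplicate fixes: exact duplicate rows are dropped; fixes sharing a
  timestamp keep the first and log the rest.
* The behavioural state of the displacement ending at a grid time is
  reported as that time's behaviour; the first grid time inherits the
  first displacement's state.
* Medians of even-length samples use the mean-of-middle convention.
* Kaplan-Meier ties: events precede censorings at equal times.
* The logistic departure curve is fit on the departure (not presence)
  scale, so its 50% point is the "50% chance of departure" quantity.
* Perfect separation in the logistic fit (e.g. everyone departs on the
  same day) is detected and raised as an error rather than returning a
  divergent slope.
* `mcp_area` returns 0 with a degeneracy flag for collinear point sets.
* R-hat with zero within-chain variance and equal means reports exactly 1.

## Problem sizes used by the tests

The shipped test-suite and acceptance script run the parameter-recovery
study at 8 animals x 30 days, dt = 2 h, with 2 chains of 10 000
iterations (8 000 burn-in, thin 2) — a deliberately scaled-down protocol
that the sampler's composite scans make adequately mixed (R-hat below
~1.1 for all parameters in the shipped configuration). Replicate-coverage
property tests use 20 smaller fits (2 animals x 8 days, single chain).
The full 50 000-iteration study protocol remains the default of
`fit_hssm()`.

## Known limitations

* Degrees-based planar state space: fine at mid-latitudes, increasingly
  distorted poleward; no antimeridian support.
* A single shared `Sigma` for both behavioural states, as in the source
  model family.
* No per-individual movement parameters (population-level only).
* Speed uncertainty is not propagated from the location posteriors into
  the kinematic series.
* The harmonic diel model cannot represent sharp crepuscular spikes;
  with two harmonics a peak narrower than ~3 h will be smeared.
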
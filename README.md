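# whaletrack

Behaviour-discriminating analysis of satellite-tracked whales: a
hierarchical two-state switching state-space model for Argos telemetry,
with the downstream ecology — departure detection, residency with
censoring, discrete area-restricted-search (ARS) areas, and diel activity
profiles — and a synthetic track generator so the whole pipeline runs
without any external data.

## Who this is for

Movement ecologists working with Argos-class animal telemetry who want a
self-contained, tested implementation of the classic two-state
first-difference correlated random walk (DCRW) with class-specific
heavy-tailed observation errors, plus the stopover-style analyses built
on top of it.

## The model

Latent locations live on a regular time grid (2 h or 4 h). Displacements
`d_t = x_t - x_{t-1}` follow a switching DCRW:

    d_t = gamma[b_t] * T(theta[b_t]) d_{t-1} + e_t,    e_t ~ N2(0, Sigma)

with behavioural state `b_t in {1 = transiting, 2 = ARS}` evolving as a
first-order Markov chain. `T(theta)` rotates the previous displacement
through the mean turn angle; `gamma` is move persistence. Transiting has
turn angles near zero and high persistence; ARS has low persistence and
frequent reversals. Argos fixes are tied to the grid by linear
interpolation and compared through independent scaled Student-t errors
whose scale and tail weight depend on the Argos location class (3, 2, 1,
0, A, B). Movement parameters are shared across the animals of a species
(the hierarchical part); paths and behaviours are per-animal. Fitting is
by Metropolis-within-Gibbs MCMC (see `vignettes/whaletrack-methods.Rmd`
for priors, sampler design and conventions).

The behavioural index `b` at each grid time is the posterior mean of the
behaviour samples: `b < 1.25` is classified transiting, `b > 1.75` ARS,
between the two uncertain.

## Worked example

Simulate a small two-regime population, fit the model with a scaled-down
MCMC protocol, classify behaviour and summarise:

```r
library(whaletrack)

cfg    <- sim_config(n_animals = 3, duration_days = 10, seed = 7)
truth  <- simulate_tracks(cfg)
tracks <- observe_tracks(truth, cfg)

fit <- fit_hssm(tracks, dt_hours = 2,
                mcmc = list(n_chains = 2, n_iter = 3000,
                            burn_in = 2000, thin = 2),
                seed = 11)
fit
#> Hierarchical switching state-space model fit (fin preset)
#>   3 animal(s), dt = 2 h
#>   MCMC: 2 chain(s) x 3000 iterations, burn-in 2000 , thin 2 -> 500 samples/chain
#>   posterior medians:
#>    theta1    theta2    gamma1    gamma2    alpha1    alpha2 sigma_lon sigma_lat
#>     0.007    -2.038     0.927     0.267     0.907     0.142     0.023     0.025
#>       rho
#>    -0.015

states <- classify_behaviour(fit)
table(states$class)
#>        ARS transiting  uncertain
#>         91        156        115

kin <- speed_series(states)
median_ars_speed(kin)
#> [1] 0.4932885
```

The posterior medians sit close to the generating values
(`gamma = (0.9, 0.3)`, `theta = (0, pi)`, `alpha = (0.95, 0.1)`): the
fitted persistence pair separates the directed mode (`gamma1 ~ 0.93`)
from the search mode (`gamma2 ~ 0.27`), and the classified series gives
the time split between transiting and ARS that the residency and diel
analyses consume. (At this deliberately small scale — three short tracks
and 3 000 iterations — the ARS turn angle and the uncertain fraction are
still loosely pinned; the shipped tests run the same recovery at 8
animals x 30 days, where the posteriors tighten markedly.) The pooled
median ARS speed (about 0.5 km/h here) is the threshold the departure
rule uses: departure is the first run of 48 consecutive hours with every
interval faster than it.

The reporting stage also works directly from published per-whale
residency tables:

```r
tab <- azores_residency_table()
fin <- tab[tab$species == "fin", ]
summarize_residency(fin, exclusions = fin$whale_id[fin$short_track])
#> $mean_residence_days
#> [1] 11.2
#> $mean_ars_percent
#> [1] 55.3
#> $n_included
#> [1] 10
```

A YAML-driven end-to-end run (simulate -> fit -> classify -> metrics ->
residency -> diel) is available as `run_pipeline(config, out_dir)`, with
a thin command-line wrapper in `inst/cli/whaletrack.R`.

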
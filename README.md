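# tpvillage

An agent-based model of cooperation in a limited-resource commons
dilemma, driven by personality rather than payoff maximisation.

A village of 150 agents shares one electricity generator that survives
only if enough villagers restrain their energy use. Each agent carries
one of seven time-perspective personality profiles (Opportunistic,
Orderly, Laborious, Steadfast, Precarious, Traumatized, Committed),
each bound to a set of interaction rules: some types cooperate and
persuade or police others, some defect and tempt, some follow the
majority or flip a coin. Two control parameters summarise social
control: `h`, the probability that a policed non-cooperator converts,
and `d`, the number of days such induced cooperation lasts.

The package is for computational social scientists and modellers who
want to study how the *distribution* of personality types in a
population shapes the group-level outcome of a social dilemma. It
ships the cross-cultural distribution of the seven profiles for 24
country samples, simulates the daily dynamics with seeded replicates,
and summarises each population by fitting the saturation curve

    y(d) = C + B exp(-d F)

to the day-100 cooperation level across habit durations d = 1..20. The
fitted equilibrium level **C** is the *cooperation index*: the level of
cooperation the population approaches as cooperative habits become
arbitrarily durable. Indices can be ranked across countries and
correlated with user-supplied country-level indicators (HDI, EPI,
Hofstede dimensions, democracy scores).

## Worked example

```r
library(tpvillage)

dists <- load_country_distributions()
sweden <- country_distribution(dists, "Sweden")
allocate_type_counts(sweden, 150)
#> t1 t2 t3 t4 t5 t6 t7
#> 23 28 32 15 31 12  9

# one seeded run: 150 agents, 100 days, h = 0.5, d = 10
ts <- run_simulation(sim_config(sweden, h = 0.5, d = 10, seed = 1))
ts
#> Cooperation time series: 150 agents, day 0..100 (compiled engine)
#>   day 0 fraction 0.473 -> day 100 fraction 0.853

# replicate-averaged day-100 cooperation at two policing strengths
low  <- run_replicates(sim_config(sweden, h = 0.30, d = 6), 200)
high <- run_replicates(sim_config(sweden, h = 0.70, d = 6), 200)
round(100 * c(low$overall_mean[101], high$overall_mean[101]), 1)
#> [1] 82.0 84.3

# the cooperation index: fit y(d) = C + B exp(-dF) over d = 1..20
fit <- cooperation_index(sweden, h = 0.5, d_max = 20, n_reps = 100)
fit
#> Equilibrium fit y(d) = C + B exp(-d F)
#>   C = 0.8470  B = -0.1968  F = 0.5205  (residual norm 1.63e-02)
```

The two percentages are the village-wide share of cooperators after
100 days: raising the conversion probability from 0.30 to 0.70 at a
six-day habit gains about two points of cooperation. Sweden's index of
about 0.85 says that even with arbitrarily durable habits roughly 15%
of the village defects at any given time, a ceiling set by its profile
mix. (Exact third decimals vary with the replicate seeds; the values
above were produced by the calls shown.)

A thin command-line front end wraps the same functions:

```sh
exec/tpvillage simulate --country Sweden --h 0.5 --d 10 --days 100 --seed 1
exec/tpvillage rank --reps 100 --seed 1 --out-dir results/
```

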
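---
title: "A personality-driven village: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A personality-driven village: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpvillage)
```

## The model

`tpvillage` simulates a commons dilemma in a small, well-mixed village:
150 inhabitants share one electricity generator that survives only if
enough of them restrain their consumption. Each day every agent holds a
binary state — cooperate (C, restrain) or defect (D, overuse) — and the
population-level outcome emerges from personality-typed interaction
rules rather than from payoff maximisation.

Agents carry one of seven time-perspective profiles (`tp_profiles()`),
cluster-derived combinations of orientations toward past, present and
future. Three profiles are unconditional cooperators:

* **Orderly (2)** and **Laborious (3)** cooperate and try to persuade
  defectors they meet (the Orderly also polices, reluctantly, half the
  time);
* **Committed (7)** cooperates and polices every defector it meets.

Four are non-cooperative to varying degrees:

* **Opportunistic (1)** defects, ignores offers, and actively tempts
  cooperators to defect;
* **Steadfast (4)** defects but copies a cooperating partner for a
  limited period, and accepts offers;
* **Precarious (5)** follows the crowd: it switches toward whichever
  behaviour the previous day's majority exhibited;
* **Traumatized (6)** is undecided, flipping state with probability one
  half when its partner disagrees with it.

Each day every agent, in a fresh random order, meets one partner drawn
uniformly from the rest of the village. The focal agent's row of the
rule table (`rule_table()`) determines its next state and any events it
directs at the partner: **policing** (social control), **offering** to
cooperate, or **tempting** to defect. Two control parameters govern the
strength of social control:

* `h` — the probability that a policed non-cooperative agent converts
  to cooperation;
* `d` — the number of days such an event-induced cooperative spell
  lasts before the agent reverts, unless a temptation ends it earlier.

The majority signal that conditions the Precarious type is the previous
day's end-of-day cooperator fraction, classified as cooperator
majority, defector majority, or tie; a tie (exactly one half) satisfies
neither condition, so majority-gated transitions simply do not fire.

## Village composition

The packaged table (`load_country_distributions()`) gives the
percentage of each profile in 24 survey samples from 22 countries plus
an aggregate row. A village is built by largest-remainder (Hamilton)
apportionment of those percentages into integer counts
(`allocate_type_counts()`): each profile receives the floor of its
quota and remaining seats go to the largest fractional remainders, ties
resolved toward the lower profile id. Apportionment is exact and
deterministic, so a country's village is identical across runs and
platforms; the alternative — multinomial sampling of profiles — would
add between-run composition variance that the downstream analyses would
then have to average away. Only the Traumatized agents' initial coin
flips (C or D with probability one half) are stochastic, and they
consume the run's seeded stream so that a single seed reproduces an
entire run.

`synthesize_distribution()` draws strictly positive percentage vectors
from a symmetric Dirichlet distribution for testing and what-if
exercises. Its single `concentration` parameter interpolates between
extreme, lopsided villages (small values) and the uniform 1/7 split
(large values); the default of 10 produces the moderate spread typical
of the packaged country rows.

## Scheduling details that matter

The verbal description of the dynamics leaves several orderings
open; the package fixes them explicitly so runs are reproducible and
divergences are traceable:

* **Sequential updates.** Agents act once each per day in a uniformly
  random order, and all state changes are visible immediately
  (asynchronous updating). Events emitted at a meeting are applied to
  the partner at once, in emission order (an Orderly agent's offer is
  applied before its optional policing).
* **One meeting per focal agent.** Every agent initiates exactly one
  meeting per day; it may additionally be chosen as a partner any
  number of times.
* **Timers.** "Cooperate for `d` days" sets a timer to `d`; at the end
  of every day each positive timer is decremented and the agent reverts
  to defection when it reaches zero — so the spell covers the event day
  plus `d − 1` further days. Re-policing or re-offering a timed
  cooperator renews the timer; temptation clears it. An agent
  cooperating *without* a timer (voluntarily) is never downgraded to a
  timed state by policing or an offer. Spells induced by the
  Precarious and Traumatized types' untimed cells stay untimed, as
  their rule cells state no duration.
* **RNG discipline.** All draws come from R's session stream in a
  fixed documented order (focal transition draw, then event draws);
  no draw is consumed when a cell's outcome is forced.

Two engines implement these semantics: a readable reference path in R
(`step_day()`, built from the exported per-cell rule functions) and a
compiled C++ core used by default. They consume random numbers
differently and so do not match run-for-run, but the test suite checks
them for statistical agreement, and checks both against an
independently transcribed rule-table oracle and, for a three-agent
village, against exact brute-force enumeration of every random branch.

## Derived quantities

`run_replicates()` averages seeded replicates (replicate *r* uses seed
`base_seed + r`) and reports pointwise means and standard errors.
Headline analyses in the documentation use 200 replicates; the test
suite scales down to 10–150 replicates and 20–100 days per run, sizes
chosen to keep Monte-Carlo error visibly below the effects asserted.

`cooperation_index()` scans habit durations `d = 1..20` at fixed
`h = 0.5`, records the day-100 overall cooperator fraction for each,
and fits the saturation curve

$$y(d) = C + B\,e^{-dF},$$

by bounded Levenberg–Marquardt least squares (`fit_equilibrium()`,
via minpack.lm) with three fixed starting points, bounds
$C \in [0, 1.5]$, $|B| \le 2$, $F \in [10^{-4}, 10]$. The bounds and
multi-start guard against the flat-likelihood trap at small $F$; a
near-constant input (standard deviation below $10^{-12}$) is returned
directly as $C = \bar y$, $B = 0$ with $F$ undefined, since the
exponential is unidentifiable there. Non-convergence is reported in the
`converged` flag, never silently swallowed. The fitted $C$ — the
cooperation level approached as habits become arbitrarily durable — is
the **cooperation index** of a profile distribution, and
`rank_countries()` orders the packaged samples by it, excluding the
aggregate row by default and breaking ties alphabetically.

Fitting over the day-100 state (rather than day-1000) follows the
observation that the dynamics show no qualitative change after the
first hundred days; `d = 0` is excluded as incompatible with a
duration measured in days. Country comparisons reuse one replicate
seed set for every distribution (common random numbers): a pure
variance-reduction device that sharpens contrasts without changing any
single country's expectation.

## Validation stage

`correlate_index()` relates the index to user-supplied country-level
indicators (human development, environmental performance, democracy
quality, Hofstede culture dimensions) with pairwise-complete Pearson
correlations, reporting the per-cell sample size. Indicator values are
deliberately **not** bundled: the editions drift over time and carry
their own licences, so the user supplies a CSV and the tests use
synthetic indicators only. Countries contributing two survey samples
must be collapsed explicitly via `average_duplicate_samples()` — the
mapping is the caller's choice, surfaced rather than guessed.
`quadratic_fit()` tests for an inverted-U association by ordinary least
squares of the index on an indicator and its square, reporting the
overall-model F statistic with (2, n − 3) degrees of freedom.

## What the synthetic generator does and does not cover

The Dirichlet generator produces valid composition vectors but not the
cross-country *correlation structure* of real samples (e.g. the
tendency of the Laborious share to covary with the Orderly share), nor
sampling error tied to the underlying survey sizes. Tests that pass on
synthetic distributions therefore certify the machinery —
apportionment, dynamics, fitting — not any empirical claim about
countries; the packaged table carries the empirical content.

## Known limitations

* The village is well-mixed; no spatial or network structure, and no
  physical environment (distance to the generator, visibility of
  neighbours) is modelled.
* There is no explicit penalty for defection; `h` and `d` summarise
  all enforcement strength.
* The exact scheduling used by other implementations of these rules
  cannot be pinned down from a verbal description alone; quantities sensitive to
  scheduling (for instance the small-`d` level of the Steadfast type
  relative to the Traumatized type) can differ between implementations
  even when every rule cell agrees. The package documents its own
  ordering precisely so such differences are attributable.
* Two rule cells are ambiguous in the source material and are resolved
  as follows: the Traumatized response to policing is timed (following
  the table's footnote over the cell text), and the Precarious
  response to an offer under a cooperator majority is untimed (the
  cell states no duration). Both choices are centralised in the rules
  module and covered by the oracle tests.
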
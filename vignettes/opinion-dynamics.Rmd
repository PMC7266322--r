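---
title: "Modelling opinion-based groups with an agreement-threshold Axelrod model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling opinion-based groups with an agreement-threshold Axelrod model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axelgroup)
```

## The model and its assumptions

Axelrod's model of cultural dissemination describes `N = L²` agents on a
square lattice, each holding a culture vector of `F` features with `q`
possible traits per feature. Interaction is homophilous: a randomly chosen
agent interacts with a random neighbour with probability equal to the
fraction of features they already share, and on interaction copies the
neighbour's trait on one differing feature. Shared culture therefore breeds
more sharing, and the dynamics freeze only when every neighbouring pair is
either identical or completely dissimilar.

This package treats the traits as *ordinal* — the structure of Likert-type
survey items, where response options sit on a scale — and adds an
**agreement threshold** `a`. In threshold mode the pair interacts with
probability equal to the fraction of features whose trait distance is at
most `a`, and only differing features within the threshold can be copied.
The threshold is the discrete analogue of bounded confidence (a latitude of
acceptance anchored at the agent's current position). Two limits pin the
behaviour and serve as built-in checks:

* `a = 0`: no copy is ever permitted; the initial state is already
  absorbing.
* `a = q − 1`: every trait pair is within reach, every interaction copies,
  and the connected lattice always collapses to full consensus.

In between, small thresholds sustain many **opinion-based groups** — sets
of agents with identical culture vectors, counted *without* requiring
lattice adjacency — even when `F` exceeds `q`, the regime where the
standard model homogenises. Because an extreme trait can only move in one
direction while a mid-scale trait can move in two, extremists are
mechanically stubborner than moderates, which keeps the model from drifting
to the scale midpoint.

The model assumes a fixed, regular interaction topology, simultaneous
random initialisation, one trait copied per event, and no noise, external
field or trait averaging; none of these assumptions is relaxed here.

## Parameters

| Parameter | Meaning | Default / range |
|---|---|---|
| `L` | lattice side; `N = L²` agents | `≥ 2`; experiments use `L = 10` (`N = 100`) and `L = 32` (`N = 1024`) |
| `F` | number of features (survey items) | `≥ 1`; sweeps cover 1–10 |
| `q` | ordered traits per feature (response options) | `≥ 2`; 5 or 7 in the headline experiments |
| `a` | agreement threshold (max trait distance that counts) | `0 … q − 1`, threshold mode only |
| `mode` | `standard` or `threshold` interaction rule | — |
| `selection_rule` | candidate-feature rule in threshold mode | `within_threshold` |
| `neighborhood` | `von_neumann` (4) or `moore` (8) | `von_neumann` |
| `max_steps` | cap on elementary events | `10⁷` |
| `check_every` | absorbing-scan cadence in events | `N · F` |

One *time step* is one elementary event — drawing `i` and `j` — whether or
not anything changes; null events advance the clock. The absorbing check is
an exhaustive `O(edges · F)` scan, cheap relative to `N · F` events, and a
`max_steps` cap guards the (never observed at these sizes, but not
impossible) case of very slow freezing; capped runs are returned flagged
`absorbed = FALSE` and kept in ensemble summaries so means are not biased
by silent exclusion.

## Design choices where the design was open

**Distance-0 features count toward the threshold-mode interaction
probability.** The probability is `|{k : |Δ_k| ≤ a}| / F`, equality
included. This mirrors how shared features count in standard mode and
guarantees the threshold-mode probability is never below the standard one;
it also makes a copy between a pair leave that pair's interaction
probability unchanged (the copied feature moves from "within threshold,
differing" to "within threshold, equal" — both count), a property the
package asserts on recorded event logs.

**Two candidate-selection readings are implemented.** The threshold rule
can be read as (i) drawing the candidate among differing features already
within the threshold (`within_threshold`, the default — no wasted draws),
or (ii) drawing among all differing features and rejecting the copy when
the distance exceeds `a` (`literal_two_stage`, a literal double check).
The sets of absorbing states coincide — both immobilise a pair exactly when
no differing feature lies within the threshold — so cluster statistics
agree; only transient kinetics differ. Both rules are exercised by the
test suite.

**Von Neumann neighbourhood by default**, as in the classic lattice model;
Moore is an option. The lattice is non-periodic, so corners have degree 2
and borders 3.

**Isolates are clusters of size 1.** Cluster sizes must partition `N`;
an agent whose culture nobody shares is a group of one. The headline
cluster statistic is always the non-spatial count; spatially connected
cultural regions (`spatial_regions()`) are provided for comparison and are
never fewer in number.

**Relaxed grouping** (`relaxed_components(state, m)`) counts connected
components of the "agree on at least `F − m` features" graph; `m = 0`
reduces exactly to identical-vector clusters. Agreement chains, so relaxed
components may contain pairs that disagree on more than `m` features —
this is the intended reading.

**Projection conventions.** The attitude-space projection weights an edge
by the number of agents co-holding both (feature, trait) endpoints; since
each agent holds one trait per feature, within-feature edges cannot occur.
Edge weights are displayed in terciles of the observed distribution, ties
assigned to the lower bin so labelling is deterministic and
order-independent; boundaries are reported. The agent-space projection
links agents sharing at least one attitude, weighted by the shared count;
display may restrict to the giant component, but exported graphs always
contain every node. Lattice-view edge classes generalise the classic
four-way styling parameterically in `F`: all shared → no line, more than
half → dotted, up to half → dashed, none → thick solid.

**Trait indexing** is 0-based internally (`0 … q − 1`); survey-style CSV
input with 1-based codes (`1 … q`) is shifted down on read.

## Randomness and reproducibility

All draws — agent, neighbour, interaction Bernoulli, candidate feature —
come from R's global RNG, so a single `set.seed()` (or the `seed` argument)
makes a run bit-reproducible. The compiled event loop and the R-level
single-event function follow the same RNG-consumption protocol (one
uniform each for agent, neighbour and the Bernoulli, plus one for the
candidate only when the pair interacts with a nonempty candidate set), and
a test asserts both produce identical trajectories from the same seed.

Ensembles derive one seed per (cell, run) from a master seed by a single
`sample.int()` draw over cells in lexicographic order; the seeds are
recorded in `runs.csv`, so any row can be re-run independently to the
identical result, and cells are mutually independent (parallel execution
would reproduce sequential results).

## What the generator emulates — and what it does not

Initial states are i.i.d. uniform over traits, the model's standard random
seeding; a goodness-of-fit test in the suite checks per-cell uniformity.
This emulates a maximally disordered survey population. Real survey data
are not uniform: responses correlate across items, marginals are skewed,
and populations are not square lattices of size `L²`. Passing tests
therefore validate the *dynamics, statistics and plumbing*, not any claim
about empirical attitude structure; seeding with real response matrices
(supported via `read_culture_csv()` for the statistics and visualisation
layers) is deliberately outside the dynamical experiments.

## Problem sizes used by the tests and acceptance script

The suite exercises the documented study conditions directly where they
are cheap (consensus limit at `L = 6`, 50 seeded runs; frozen limit;
exhaustive absorbing-state enumeration on ≈100 terminated runs; 200 random
matrices for the cluster oracles). For the ensemble trends the package's
own scaled profile is 200 runs per cell at `q = 5`, `N = 100` over
`F ∈ {2, 4, 8}` × `a ∈ {1, 2, 3}` — large enough that the rise of the mean
cluster count in `F` and its fall in `a` exceed twice the combined
standard errors with margin, small enough to run routinely. Headline
figures at 1,000 runs per cell and `N = 1024` use the same code path via
`ensemble_spec(n_runs = 1000, L_grid = 32)`.

## Known limitations

* Only the non-periodic square lattice is implemented; other topologies,
  noise, media fields, multilayer coupling, per-feature `q` and
  trait-averaging interactions are out of scope.
* The dense pairwise shared-feature matrix in `relaxed_components()` is
  `O(N² F)`; fine to `N ≈ 10³`, not meant for much larger populations.
* Steps-to-absorption comparisons between modes are reported, not
  guaranteed: the threshold model tends to freeze faster at matched
  parameters, but the package treats this as an observed tendency.
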
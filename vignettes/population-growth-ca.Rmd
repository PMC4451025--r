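---
title: "Mechanistic population growth on a lattice: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic population growth on a lattice: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popca)
```

## The model

`popca` models a single vegetatively propagating plant species on a lattice
of microhabitats. A microhabitat is the parcel of resources that supports
exactly one individual (one grass tiller); rhizome growth places offspring
into neighboring microhabitats. The model is a logical, deterministic,
individual-based cellular automaton with four site states — free (0),
occupied (1), regenerating (2) and boundary (3) — updated synchronously:

* a free or regenerating site becomes occupied when **at least one** site of
  its neighborhood holds a living individual;
* every individual dies after exactly one iteration, leaving its site in the
  regenerating state;
* a regenerating site that is not recolonized becomes free again after one
  iteration;
* boundary cells never change and never count as occupied.

This is the rest/excited/refractory formalism of excitable media: the free
state is rest, a living individual is the excitation, and regeneration is
the refractory phase during which the microhabitat recycles the dead
individual's resources (it may nonetheless be recolonized directly,
2 → 1). All three states last exactly one iteration; longer lifetimes or
regeneration times would require additional states and are out of scope.

### Assumptions

* Synchronous, deterministic updating: given a configuration and an initial
  placement, a run is perfectly reproducible. The only randomness anywhere
  in the package is Monte Carlo sampling of initial positions.
* Homogeneous habitat: every interior site is an identical microhabitat.
* One founder: runs start from a single occupied site (`init = "center"` by
  default, i.e. 0-based `(⌊(H−1)/2⌋, ⌊(W−1)/2⌋)`).
* Iteration numbering starts at `t = 0` for the initial state, so a
  population series `1, 3, 6, ...` has its founder at `t = 0`.

## Neighborhoods and the lattice embedding

The hexagonal lattice is embedded *axially* on a square index array: every
site `(i, j)` has the same six offsets
`(0,±1), (±1,0), (1,1), (−1,−1)`, with no row-parity alternation. Under this
convention the number of sites at hex-distance `k` is `6k` (checked by
brute-force enumeration in the tests), which is exactly what produces the
colonization series `1, 6, 13, 24, 37, 54`. Row-parity ("offset
coordinate") hexagonal dialects would break this count and are deliberately
not supported.

The tripod neighborhood is the zero-sum 3-subset `(0,1), (1,0), (−1,−1)` of
the hexagonal set. Its literal orientation is a free choice — any rotation
or reflection is dynamically equivalent for population counts — but the
zero-sum property matters: it is what makes single-founder growth follow the
triangular numbers `1, 3, 6, 10, 15, 21`. The fecundity (maximum offspring
per individual per iteration) equals the neighborhood size: 6 for hexagonal
(aggressive propagation), 3 for tripod (moderate propagation). Conventional
von Neumann and Moore neighborhoods are included for completeness.

Colonization is evaluated on the target site's **own** (incoming)
neighborhood. For the symmetric hexagonal set this is identical to the
outgoing "offspring" reading; for the asymmetric tripod the offspring
footprint is the reflected offset set, and all population counts are
unaffected by the reflection.

Boundary modes: `torus` wraps both indices (no boundary effects);
`bounded` surrounds the interior with a one-cell frame of boundary-state
sites, which blocks waves the way the edge of a field plot does.

## Closed-form references

On an unbounded lattice the wavefront advances one hex-distance per
iteration and the one-iteration lifetime leaves occupied rings at
alternating distances `t, t−2, t−4, … ≥ 0`. With ring sizes `6k` this gives

* hexagonal: `N(t) = 3(t+1)²/2` (odd `t`), `N(t) = 1 + 3t + 3t²/2`
  (even `t`);
* tripod: `N(t) = (t+1)(t+2)/2`.

These closed forms are the package's analytic oracle: torus runs must equal
them for every `t` with `2t + 1 ≤ min(H, W)` (the wavefront untouched by
wrap-around; the bound is conservative), and the tests assert this up to
`t = 12` for both neighborhoods. The J-shaped reference (`geometric_series`)
is `N(t) = n₀ · f^t`: every individual leaves exactly `f` offspring and
dies, with no competition for sites. `comparison_table()` juxtaposes the
two; the gap from `t = 2` on measures how strongly intraspecific competition
for microhabitats limits growth.

## Curve phenomenology: operationalizations

The automaton is deterministic and finite, so every run enters a limit
cycle. `ca_run()` hashes the full lattice state each iteration and stops at
the first recurrence, reporting the transient `T` (first iteration whose
state recurs) and period `P`.

**Plateau onset.** The plateau of a growth curve is operationalized as the
entry of the *population series* into exact periodicity with period `P`:
the smallest `t0 ≤ T` such that `N(t) = N(t+P)` for all `t ≥ t0`. This is
parameter-free and exact, and accommodates fluctuating plateaus (period-1
plateaus are fluctuation-free). The population series can become periodic
one step before the full lattice state does — a single count can
coincidentally match its periodic extension while the pattern still differs
— so both readings are exposed (`plateau_onset()` and the `state_transient`
column of `curve_features()`). On the 50×50 reference habitats the two
readings differ by at most one iteration; where a published, visually-read
onset falls between them, the package reports both rather than tuning either
definition.

**Transient plateaus.** A transient plateau is a maximal interval, strictly
before the final plateau, in which successive counts change by at most
`tol`. The default tolerance is the fluctuation amplitude of the run's own
final plateau (max − min over one cycle): a transient plateau is a stretch
where the population fluctuates no more than it does on the true plateau.
This choice is parameter-free and self-consistent; a strict `tol = 0` would
be blind to transient plateaus that carry the same small oscillation as the
final plateau, which is precisely what the double-S tripod-torus curve does
(its first plateau oscillates by ±2, like its final one). The minimum
length is 3 iterations, below which a flat stretch is indistinguishable
from a single slow step of the integer series.

**Classification.** `J` for an exactly constant growth ratio (or a series
that never plateaus within budget) — only the geometric model produces J
curves; `double-S` when at least one transient plateau precedes the final
plateau; `S` otherwise.

**Boundary hit.** `deviation_onset()` reports the first iteration at which
a run's occupied count departs from a reference series, e.g. the unbounded
closed form; for bounded habitats this is the iteration at which the
population waves reach the frame.

**Free-area extinction.** "Areas consisting only of free microhabitats" is
operationalized two ways, which bracket the event on the reference runs:

* `free_core_count()` / `free_core_extinction()`: free sites whose entire
  neighborhood is also free — a local, neighborhood-consistent proxy for
  virgin territory;
* `free_region_extinction()`: the first iteration with no connected region
  of ≥ 2 free sites left (hexagonal adjacency, the natural adjacency of the
  lattice) — after it, only isolated free vacancies inside the populated
  waves persist.

On the 50×50 tripod torus the two readings give consecutive iterations (48
and 49); both are computed by the test suite.

## Monte Carlo over initial placements

`positions_for()` enumerates every interior site (`"all"`) or samples `n`
distinct sites uniformly without replacement under a caller-supplied seed;
`run_ensemble()` runs the deterministic engine once per position and
aggregates per-iteration min/mean/max/sd of the occupied count. Ensembles
are exhaustive by default for lattices up to 23×23 (at most 529 runs,
seconds of work), which strengthens the invariance checks at no real cost;
for larger lattices, sampling 100 positions matches common practice for this
design. On a torus the census series is translation invariant, so every
ensemble is degenerate (`identical_series = TRUE`, sd ≡ 0); with a boundary,
placements near the frame lose part of their neighborhood's reach earlier,
and replicate series differ.

## Numerical and degenerate-input choices

* Cycle detection keys the flattened grid; memory is trivial at the
  package's scales (≤ 98×98 and a few thousand iterations).
* Budget exhaustion before a recurrence is reported
  (`cycle_detected = FALSE`), not raised; plateau analysis then refuses with
  an informative error.
* Neighbor lists are ordered deterministically, so snapshots and traversals
  are reproducible; order never affects the dynamics (the colonization test
  is any-neighbor).
* A 1×1 bounded habitat founder dies without issue (occupied →
  regenerating → free forever); an all-free lattice is a fixed point.
* Bounded mode supports offsets within the one-cell frame (all built-in
  neighborhoods); wider custom offsets are rejected up front.

## Problem sizes

The test suite works at the scales the phenomenology needs and no more:
50×50 habitats for the reference growth curves (runs enter their cycles
before iteration 110; budgets of 400 leave ample headroom), 23×23 for
exhaustive ensembles and invariance checks, 27×27 for the closed-form
oracle up to `t = 12`, and 3–16 side lengths for classification and
steady-plateau checks. The full suite runs in well under two minutes; the
acceptance script in about two seconds.

## What passing tests do and do not show

The simulations are the model itself, not synthetic stand-ins for field
data, so agreement with the printed trajectories is an exact property of the
implementation — it says nothing about how well one-iteration lifetimes, a
homogeneous habitat, or deterministic colonization describe a real lawn.
Real grass populations have variable tiller lifetimes and regeneration
times (representable here only by adding states), environmental
heterogeneity and stochastic mortality, none of which the model includes.

## Known limitations

* Single species only; no interspecific competition.
* All state durations fixed at one iteration.
* `3N×3N` tripod tori have fluctuation-free *population* plateaus while the
  lattice pattern itself keeps translating with state period 3; plateau
  steadiness must therefore be judged on the census (fluctuation amplitude
  0), not on the full-state period.
* The plateau-onset and free-area events admit more than one reasonable
  operationalization; the package computes the alternatives rather than
  committing to a visually-read value.
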
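# popca

Deterministic cellular-automaton models of single-species population growth.

`popca` simulates the vegetative spread of a clonal plant (one tiller = one
individual = one occupied microhabitat) as a purely logical, deterministic,
individual-based cellular automaton, and reproduces the growth-curve
phenomenology that emerges from it: S-shaped and double S-shaped sigmoid
growth, fluctuating and fluctuation-free plateaus, and the J-shaped
geometric reference model that the automaton is compared against. It is
aimed at theoretical and population ecologists who want a mechanistic
(individual-based) counterpart to phenomenological growth models such as the
Malthusian and Verhulst equations.

## The model

Each lattice site is a microhabitat in one of four states,

| state | code | meaning |
|---|---|---|
| free | 0 | at rest, colonizable |
| occupied | 1 | a living individual |
| regenerating | 2 | recycling a dead individual's resources |
| boundary | 3 | impassable frame cell (bounded habitats only) |

updated synchronously by the birth–death–regeneration rules

```
0 -> 1   if at least one site of the neighborhood is occupied, else 0 -> 0
1 -> 2   always (an individual lives exactly one iteration)
2 -> 1   if at least one site of the neighborhood is occupied, else 2 -> 0
3 -> 3   always
```

This is the rest / excited / refractory scheme of excitable-medium theory:
colonization propagates as self-sustaining population waves. Two
neighborhoods set the fecundity *f* (maximum offspring per individual per
iteration): **hexagonal** (*f* = 6, aggressive propagation) and **tripod**
(*f* = 3, moderate propagation), embedded axially on a square index array.
Habitats are either a torus (no boundary effects) or bounded by a frame of
boundary cells.

On an unbounded lattice the occupied population has the closed forms
N(t) = 3(t+1)²/2 (hexagonal, odd t), N(t) = 1 + 3t + 3t²/2 (hexagonal,
even t) and N(t) = (t+1)(t+2)/2 (tripod), against the J-shaped geometric
model N(t) = n₀·f^t of unlimited growth. The automaton is deterministic and
finite, so every run enters a limit cycle; the package detects it, locates
the plateau onset of the growth curve, finds transient plateaus, and
classifies curves as J, S or double-S. A Monte Carlo layer sweeps initial
placements (the package's only source of randomness).

## Worked example

```r
library(popca)

cfg <- lattice_config(50, 50, boundary = "torus", neighborhood = "tripod")
run <- ca_run(cfg, init = "center", snapshot_every = 1)
run
#> <ca_run> 50x50 torus, tripod, start (24,24), 100 iterations
#>   limit cycle: transient 98, period 2

tidy(run)$n_occupied[1:6]
#> [1]  1  3  6 10 15 21

curve_features(run)
#> # A tibble: 1 x 8
#>   plateau_onset state_transient period fluctuation_amplitude ...
#> 1            97              98      2                     2
#> # classification "double-S", one transient plateau, max_population 1251

transient_plateaus(run)
#> # A tibble: 1 x 2
#>   start length
#> 1    48      5

free_core_extinction(run)    # free cores (all-free neighborhoods) gone
#> [1] 48
free_region_extinction(run)  # last connected free area (>= 2 sites) gone
#> [1] 49
```

The occupied series starts as the triangular numbers 1, 3, 6, 10, 15, 21 —
the tripod closed form — then bends into a double S: colonization of virgin
territory ends around iteration 49, producing a 5-iteration transient
plateau (iterations 48–52) before wave interpenetration compacts the
population to its final plateau (series periodic from iteration 97, full
state from 98, fluctuating by 2 individuals with period 2).

The same comparison against unlimited growth, as printed by
`comparison_table("hexagonal", 5)`:

```
t   ca   geometric
0    1           1
1    6           6
2   13          36
3   24         216
4   37        1296
5   54        7776
```

Intraspecific competition for microhabitats is what separates the rows from
t = 2 on.

A thin command-line wrapper is installed with the package
(`system.file("cli", "popca", package = "popca")`), with subcommands `run`,
`montecarlo`, `geometric`, `table` and `analyze`; see `popca --help`.

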
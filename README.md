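# evograph

Fixation probabilities under weak selection on weighted graphs, for the
Birth-death Moran process.

## What problem this solves, and for whom

Spatial population structure changes how natural selection and genetic
drift play out. Modelling the population as a graph — one haploid
individual per vertex, reproduction along weighted edges — the central
quantity is the fixation probability `rho(r)` that a single mutant of
fitness `r` sweeps the population. Computing it exactly costs a linear
solve over all `2^N` occupancy states, which caps exact work at toy sizes.

Most real mutations are nearly neutral. In the weak-selection regime
`r = 1 + delta` the expansion

    rho(1 + delta) = rho0 + delta * rho' + O(delta^2)

reduces the problem to two quantities that this package computes in
polynomial time on any strongly connected weighted digraph:

* `rho0`, the neutral fixation probability, from *reproductive values*
  `pi_i` solving `T_i pi_i = sum_j p_ij pi_j`, `sum_i pi_i = 1`, where
  `p_ij = w_ij / w_i` are random-walk step probabilities and
  `T_i = sum_j p_ji` are vertex *temperatures*;
* `rho'`, the weak-selection coefficient, from pair *coalescence times*
  `tau_ij` solving the `N(N-1)/2`-unknown linear system

      tau_ij = [ N(mu_i + mu_j) + sum_k (p_ki tau_kj + p_kj tau_ki) ] / (T_i + T_j)

  followed by `rho' = (1/2N) sum_ij p_ij pi_j tau_ij`, where `mu` is the
  placement distribution of the initial mutant (uniform `1/N`, or
  temperature `T_i/N` for mutations arising in new offspring).

On that foundation the package classifies graphs as absolute/relative
amplifiers or suppressors of weak selection, surveys complete sets of
small connected graphs, provides closed forms for the Star, complete
bipartite, Cartwheel and Fan families, an exact `2^N`-state solver and
Monte Carlo simulator for small graphs, deterministic Detour/Cartwheel
parameter scans, and a genetic-algorithm search for extremal structures.
It is aimed at researchers in evolutionary graph theory and theoretical
population genetics.

## Worked example

```r
library(evograph)

g <- star_graph(9)          # hub plus 9 leaves, N = 10
g
#> <evograph: 10 vertices, undirected, unweighted, 9 edges>

ws <- weak_selection(g, "temperature")
str(ws)
#> List of 5
#>  $ N        : int 10
#>  $ scheme   : chr "temperature"
#>  $ rho0     : num 0.022
#>  $ rho_prime: num 0.169
#>  $ ratio    : num 7.7
```

A well-mixed population of the same size has `rho0 = 1/10 = 0.1` and
`rho' = 9/20 = 0.45`, so the Star drastically slows both neutral drift
(`rho0 = 0.022`) and selection (`rho' = 0.169`) — but the *ratio*
`rho'/rho0 = 7.7` beats the well-mixed `(N-1)/2 = 4.5`: relative to the
neutral substitutions that fix, beneficial ones are enriched.

```r
classify_graph(g, "temperature")$classification
#> [1] "absolute suppressor, relative amplifier"

cartwheel_scan(12)$best     # strongest absolute amplifier in the family
#>   n m h    rho0 rho_prime ratio
#> 1 4 2 4 0.06845    0.4937 7.213

exact_fixation(star_graph(9), c(1, 1.1), "temperature")  # exact, 2^10 states
#> [1] 0.02195 0.04146
```

The scan result says: among Cartwheels of size 12 (hub clique of `h`
vertices, `n` islands of `m` vertices, spokes of weight 1), the `4,2,4`
member has `rho' = 0.4937 > 11/24`, an absolute amplifier of weak
selection. The exact solver confirms the weak-selection line: from
`rho(1) = 0.02195` the Star's fixation probability climbs at slope
`~0.169` per unit fitness, i.e. `rho(1.1) = 0.04146 ≈ rho0 + 0.1 rho'`.

A command-line wrapper exposes the same operations
(`exec/evograph classify --family star --n 9 --scheme temperature`,
`... survey --graph6 graphs.g6`, `... scan --kind detour --N 100`, etc.),
emitting JSON.

## Package tour

| Area | Functions |
| --- | --- |
| Graph model & structure | `evograph()`, `step_probabilities()`, `temperatures()`, `is_strongly_connected()`, `is_isothermal()` |
| Families | `star_graph()`, `complete_bipartite_graph()`, `cartwheel_graph()`, `detour_graph()`, `fan_graph()`, `lollipop_graph()`, `balloon_graph()`, `balloon_star_graph()`, `make_family()` |
| I/O & fixtures | `parse_graph6()`, `format_graph6()`, `read_graph()`, `write_graph()`, `atlas_graphs()`, `random_connected_graph()` |
| Neutral drift | `init_distribution()`, `reproductive_values()`, `neutral_fixation()` |
| Weak selection | `coalescence_times()`, `weak_selection_coefficient()`, `weak_selection()` |
| Classification & surveys | `classify_graph()`, `survey_graphs()`, `survey_table()`, `extremal_graphs()` |
| Exact oracle | `exact_fixation()`, `finite_difference_rho_prime()`, `simulate_fixation()`, `fixation_difference_curve()` |
| Closed forms | `isothermal_fixation()`, `star_closed_form()`, `bipartite_closed_form()`, `cartwheel_limit_rho_prime()`, `cartwheel_limit_fixation()`, `spider_limit_fixation()`, `fan_closed_form()`, `pavlogiannis_bound()` |
| Search & scans | `genetic_search()`, `detour_scan()`, `cartwheel_scan()` |
| CLI | `run_cli()`, `exec/evograph` |

The methods vignette (`vignettes/weak-selection-on-graphs.Rmd`) documents
the model, the solvers (including the automorphism-orbit reductions that
make size-100+ family scans fast), numerical tolerances, design
decisions, and known limitations.
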
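---
title: "Weak selection on graph-structured populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak selection on graph-structured populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evograph)
```

## The model

`evograph` studies the Birth-death (Bd) Moran process on a weighted,
strongly connected graph. Each vertex hosts one haploid individual;
residents have fitness 1 and a mutant type has fitness $r$. At each time
step an individual $i$ is chosen to reproduce with probability proportional
to its fitness, and its offspring replaces a neighbour $j$ chosen with the
random-walk step probability $p_{ij} = w_{ij}/w_i$, where
$w_i = \sum_j w_{ij}$ is the weighted out-degree. The process is a finite
absorbing Markov chain; the quantity of interest is the fixation
probability $\rho_G(r)$ that a single mutant lineage takes over the whole
population.

The *temperature* of a vertex, $T_i = \sum_j p_{ji}$, is the expected
number of times it is replaced per step; temperatures always sum to $N$.
Where the first mutant arises matters, so the package supports three
placement schemes for the initial mutant: **uniform** ($\mu_i = 1/N$,
mutations strike standing individuals equally), **temperature**
($\mu_i = T_i/N$, mutations arise in new offspring, hence more often at
frequently-replaced sites), and arbitrary custom distributions.

## Weak selection in polynomial time

Computing $\rho_G(r)$ exactly requires solving a linear system over all
$2^N$ occupancy states, which is hopeless beyond small $N$. Most non-lethal
mutations, however, are nearly neutral, and in the weak-selection regime
$r = 1 + \delta$, $|\delta| \ll 1$, the expansion

$$\rho_G(1 + \delta) = \rho^\circ + \delta\,\rho' + O(\delta^2)$$

reduces the problem to two quantities that are computable in polynomial
time:

* **Neutral fixation probability** $\rho^\circ$. The fixation probability
  $\pi_i$ of a neutral mutant placed at vertex $i$ (its *reproductive
  value*) solves the balance system $T_i \pi_i = \sum_j p_{ij} \pi_j$
  together with $\sum_i \pi_i = 1$; then
  $\rho^\circ = \sum_i \mu_i \pi_i$. On undirected graphs
  $\pi_i \propto 1/w_i$ in closed form. Under uniform initialization
  $\rho^\circ = 1/N$ on every graph; under temperature initialization
  $\rho^\circ \le 1/N$ with equality exactly on isothermal graphs
  (all $T_i = 1$), so structure can only slow the neutral molecular clock.

* **Weak-selection coefficient** $\rho'$. Under neutrality the ancestral
  lineages of two vertices perform coalescing random walks. The rescaled
  pair coalescence times $\tau_{ij}$ solve, over unordered pairs,

  $$\tau_{ij} = \frac{N(\mu_i + \mu_j) + \sum_k (p_{ki}\tau_{kj}
    + p_{kj}\tau_{ki})}{T_i + T_j}, \qquad \tau_{ii} = 0,$$

  a linear system with $N(N-1)/2$ unknowns, and then
  $\rho' = \frac{1}{2N} \sum_{i,j} p_{ij}\, \pi_j\, \tau_{ij}$. On
  undirected graphs this equals the degree-weighted form
  $\frac{1}{2N\widetilde W} \sum_{i,j} \frac{w_{ij}}{w_i w_j} \tau_{ij}$
  with $\widetilde W = \sum_i w_i^{-1}$. The reproductive-value weighting
  is the package's generalization to digraphs; it reduces exactly to the
  undirected form and is validated against a finite-difference oracle on
  random digraphs in the test suite.

A note on the grouping of the recurrence: the whole numerator is divided
by $T_i + T_j$. This grouping is forced by internal consistency — with
$\mu = T/N$ the recurrence must reduce to the familiar
"$1 + \dots$" coalescence-time form, and on $K_2$ it must give
$\tau_{12} = 1$ (a pair of individuals coalesces in exactly one
replacement event).

## Amplifiers and suppressors

Every isothermal graph has $\rho^\circ = 1/N$ and
$\rho' = (N-1)/(2N)$. Against that baseline a graph is an

* **absolute amplifier** if $\rho' > (N-1)/(2N)$ (fitness increases
  fixation probability faster than in a well-mixed population), an
  **absolute suppressor** if $\rho' < (N-1)/(2N)$;
* **relative amplifier** if $\rho'/\rho^\circ > (N-1)/2$, a **relative
  suppressor** otherwise. The ratio $\rho'/\rho^\circ$ governs how many
  beneficial substitutions accrue per neutral one, in the spirit of
  dN/dS-type ratios.

Under uniform initialization the two notions coincide
($\rho^\circ = 1/N$). Under temperature initialization
$\rho^\circ \le 1/N$ implies $\rho'/\rho^\circ \ge N\rho'$, which rules
out "absolute amplifier + relative suppressor"; the three remaining
combinations all occur, and `classify_graph()` reports them with fixed
labels.

```{r}
classify_graph(star_graph(9), "temperature")[c("rho0", "rho_prime", "ratio",
                                               "classification")]
```

## Numerical design

**Solvers.** The pair system is solved three ways, all agreeing to
solver tolerance: dense LU (default for $N \le 60$), sparse LU via
`Matrix` (larger graphs), and an **orbit-reduced** solver. Family
constructors attach generators of their automorphism groups; pairs of
vertices are grouped into orbits by union-find over generator images, and
the linear system is solved on orbit representatives only. This is an
exact reduction, not an approximation — the solution is automorphism
invariant because it is unique and the system is equivariant. It is what
makes parameter scans over highly symmetric families (Detour graphs of
size 100, Cartwheels of size 140) run in seconds. Every solver verifies
the recurrence residual ($< 10^{-8}$ relative) before returning.

**Exact oracle.** For $N \le 14$, `exact_fixation()` solves the
$2^N$-state absorbing chain directly (sparse, bitmask-ordered states,
absorbing states eliminated). Mutant-birth transition weights enter
linearly in $r$, so the assembled structure is reused across fitness
values when tracing curves or root-finding. When automorphism generators
are present the state space is first lumped into occupancy-state orbits —
again an exact reduction (symmetric states have equal absorption
probability), which turns the $4096$-state Cartwheel computation into a
few-hundred-state solve. A Monte Carlo simulator (`simulate_fixation()`)
provides a model-level cross-check at sizes where even $2^N$ is
infeasible.

**Classification tolerance.** Survey counts must be integers, so
borderline arithmetic is treated conservatively: isothermality is decided
structurally (regularity, for unweighted undirected graphs; exact
temperature equality for weighted ones), never by comparing float
$\rho'$ against a threshold. For the remaining graphs the classification
margin — the distance of $\rho'$ and $\rho'/\rho^\circ$ from their
thresholds — is monitored, and a survey refuses to classify any graph
with margin below $10^{-9}$ rather than silently guessing. On the
complete sets of connected graphs up to size 7 the smallest observed
margin is above $10^{-6}$, several orders of magnitude beyond solver
error, so the guard never triggers at these sizes.

**Closed forms.** The Star, complete bipartite, small-spoke Cartwheel,
spider-limit and Fan expressions in `R/closed_forms.R` were derived
symbolically from the same balance and coalescence systems (for the Fan,
blade symmetry reduces the pair system to three unknowns, which we solved
with a computer algebra system and transcribed as rational functions).
Each closed form is gated by a release test requiring agreement with the
numeric pipeline to $10^{-9}$ across a parameter grid
($n, m \in \{2,3,4\}$, $\epsilon \in \{0.1, \epsilon_{\mathrm{iso}}, 1,
10\}$ for the Fan), plus the family's known limits: the Fan is isothermal
at $\epsilon = (m-1)/(mn-1)$, approaches the Star $S_{nm}$ as
$\epsilon \to \infty$, and $\rho' \to (m+1)/(2m)$ as $n \to \infty$.

For the general ($h \ne m$) Cartwheel in the $\epsilon \to 0$ limit no
closed form for the full fixation curve is exposed: the candidate
expression could not be transcribed reliably, so
`cartwheel_limit_fixation()` serves the exact well-mixed reduction at
$h = m$, the Taylor data ($\rho^\circ = 1/N$ and the slope from
`cartwheel_limit_rho_prime()`), and otherwise evaluates the exact solver
at a small spoke weight ($\epsilon = 10^{-6}$, with $10^{-7}$ available
to confirm convergence) for $N \le 14$. The slope formula itself carries
the sign of $h - m$: hub-heavy cartwheels amplify, island-heavy ones
suppress, and $h = m$ recovers the well-mixed process exactly.

**Degenerate inputs.** Graphs with a zero out-degree vertex are rejected
(the replacement walk is undefined); disconnected graphs are rejected by
every analysis entry point; self-loops are representable and handled by
the solvers but produced by no constructor. Custom placement vectors must
sum to one within $10^{-12}$.

## Random fixtures: what they do and do not emulate

`random_connected_graph()` draws Erdős–Rényi-type graphs (optionally
directed, optionally with i.i.d. Uniform(0.1, 2) edge weights),
resampling until strongly connected, deterministically for a given seed.
These fixtures exist to exercise the solvers across the full input class
the theory covers — arbitrary strongly connected weighted digraphs — and
to drive the oracle-equivalence property tests. They are not models of
any real spatial population: real structures (lattices, metapopulations,
tissue architectures) are far from Erdős–Rényi. Passing tests therefore
certify the *computation* on arbitrary graphs, not any biological claim
about particular structures; for the latter, the named families and the
survey machinery are the relevant tools.

## Problem sizes

The package's own test battery uses desk-scale problem sizes chosen to
keep the full suite fast while still covering every code path: complete
surveys to size 7 (853 graphs at $N = 7$; the enumeration source is
igraph's built-in atlas, which ends at 7 vertices — larger surveys accept
graph6 files from standard generators), oracle equivalence on the
complete atlas to $N = 5$ plus 200 seeded random weighted digraphs to
$N = 6$, the Detour scan at $N = 100$, and the Cartwheel family to
$N = 140$ via the orbit-reduced solver. Published survey counts for sizes
8–10 (up to 11.7 million graphs) are reachable with the same code given a
graph6 stream and cluster time, but are deliberately out of the default
test envelope.

## Genetic search

For sizes beyond exhaustive enumeration, `genetic_search()` evolves an
ensemble of simple connected graphs toward an extreme of $\rho'$ or
$\rho'/\rho^\circ$: truncation selection (population 100, top 20 survive,
5 elites copied unchanged), per-pair uniform crossover of adjacency
indicators, independent edge toggling with probability $2/(N(N-1))$ (two
expected toggles per offspring), connectivity repair by inserting random
edges between components, 200 generations by default. All parameters sit
in the call signature; the defaults are conventional choices for this
kind of graph search rather than a calibrated setting. Elitism makes the
best score monotone across generations, which the tests assert, along
with seed-determinism and the identity between reported scores and
recomputation through `classify_graph()`. Scores are cached by canonical
form (igraph's canonical permutation) to avoid rescoring isomorphic
candidates.

## Known limitations

* Only Birth-death updating is implemented; death-Birth and other update
  rules have different (and sometimes opposite) amplification behaviour.
* The weak-selection expansion says nothing about $\rho(r)$ far from
  $r = 1$; the exact solver covers that regime only to $N \le 14$.
* Exhaustive surveys are exact but enumeration-bound; sizes above 10 are
  out of practical reach for complete classification anywhere.
* Exact-rational arithmetic is not used; instead the margin guard above
  makes any numerically ambiguous classification loud rather than wrong.
* Fixation *times* are not computed.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from scratch against the installed
package: the complete size-6 and size-7 survey counts under both
initialization schemes, the Cartwheel $CW_{2,5,2}$ crossing fitness via
the exact solver at $\epsilon = 10^{-6}$ (stability-checked at
$10^{-7}$), the ratio-minimizing Detour path length at $N = 100$, and the
limiting Star $\rho'$ under uniform initialization, writing one JSON
record per quantity. See the README for invocation.
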
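---
title: "Quantifying small-world structure with the Small-World Propensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying small-world structure with the Small-World Propensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swprop)
```

## The problem

A small-world network combines lattice-like local clustering with
random-graph-like short paths. The classical way to diagnose it, the
small-world index $\sigma = (C/C_{rand}) / (L/L_{rand})$, has two well-known
defects when applied to empirical data such as brain networks: it is strongly
density dependent ($C_{rand}$ collapses toward zero in sparse networks,
inflating $\sigma$ over a huge range of topologies), and it ignores edge
weights entirely. Both defects matter in neuroscience, where networks are
compared across development, disease, and imaging modalities that differ
precisely in density and in the distribution of connection strengths.

The Small-World Propensity (SWP) addresses both. The observed clustering
coefficient $C_{obs}$ and characteristic path length $L_{obs}$ are compared
against *both* null extremes — a lattice and a random network constructed at
the same size and with the same edge-weight distribution — and expressed as
bounded fractional deviations:

$$
\Delta_C = \frac{C_{latt} - C_{obs}}{C_{latt} - C_{rand}}, \qquad
\Delta_L = \frac{L_{obs} - L_{rand}}{L_{latt} - L_{rand}},
$$

each clamped to $[0, 1]$ (observed networks occasionally fall outside the
null range; the raw values and clamp flags are kept for diagnostics). The
propensity is the complement of the root-mean-square deviation:

$$
\phi = 1 - \sqrt{\frac{\Delta_C^2 + \Delta_L^2}{2}} \in [0, 1].
$$

Because the deviations are normalised by the range the nulls span *at the
observed density*, $\phi$ remains comparable across densities. A pure lattice
($\Delta_C = 0$, $\Delta_L = 1$) and a pure random network ($\Delta_C = 1$,
$\Delta_L = 0$) both score $\phi = 1 - \sqrt{1/2} \approx 0.29$:

```{r corners}
small_world_propensity(0, 1)
small_world_propensity(1, 0)
```

A companion statistic summarises *which* deviation drives the score. With
$\theta = \arctan(\Delta_L / \Delta_C)$ the angle of the deviation vector,

$$
\delta = \frac{4\theta}{\pi} - 1 \in [-1, 1],
$$

so $\delta = +1$ means the deficit is entirely path-length-driven (a
lattice), $\delta = -1$ entirely clustering-driven (a random network), and
$\delta = 0$ equal contribution. $\delta$ depends only on the direction of
the vector, not its length; at the degenerate origin $(0, 0)$ it is defined
as 0 by symmetry.

## Raw statistics and their weighted forms

`clustering_coefficient()` averages per-node triangle-closure coefficients
over *all* nodes (nodes with fewer than two neighbours contribute 0, keeping
the average comparable across networks with leaves). Three weighted variants
are available — `"onnela"` (subgraph intensity, the default), `"barrat"`
(strength-weighted), and `"zhang"` (purely weight-based) — all reducing
exactly to the binary coefficient on binary networks. Onnela and Zhang
normalise by the maximum weight of the matrix under evaluation, so each
network is normalised in isolation and the coefficients are invariant under
a common rescaling of all weights.

`char_path_length()` averages shortest-path distances over ordered node
pairs. In weighted mode the cost of traversing an edge is the reciprocal of
its weight, $d_{ij} = 1/w_{ij}$: in structural brain networks a high
streamline density means information flows easily, and in functional networks
a high correlation means two regions are close in similarity space, so in
both cases strong edges should be cheap. Unreachable pairs are excluded from
the mean and reported in `n_unreachable_pairs` (disconnected empirical
matrices are common; a `strict` flag escalates to an error instead).

## Generating weighted small-world networks

Brain networks are spatially embedded, and edge strength falls off with
physical distance. The weighted Watts-Strogatz model mirrors this: nodes sit
on a ring, every node links to its neighbours within radius $r$, and each
edge gets a weight decreasing with the ring distance $d$ of its endpoints,

$$
w(d) = \frac{D_{max} - d}{D_{max}}, \qquad D_{max} = \max_{i,j}\, d_{ij} + \epsilon,
$$

where the maximum runs over all node pairs ($\lfloor N/2 \rfloor$ on a ring)
and $\epsilon$ is one unit of lattice spacing — the measurement precision for
a lattice standing in for real data — which guarantees every weight is
strictly positive. The functional form is a package choice satisfying the
model's constraints (strictly decreasing, positive, dimensionless); it is
exposed as the pluggable `weight_fn` argument of `weighted_ring_lattice()`
so any other decreasing map can be substituted without code changes. The
downstream statistics are insensitive to the particular map because Onnela
clustering renormalises weights and the null models conserve the weight
multiset whatever it is.

Rewiring (`rewire_edges()`) then selects each edge independently with
probability $p$, detaches it at its second endpoint and reattaches it
uniformly among the non-neighbours of the kept endpoint, *carrying the weight
unchanged*. Edge count and weight multiset are conserved exactly for every
$p$, so the family interpolates from a weighted lattice ($p = 0$) to a
weighted random network ($p = 1$) at constant weight distribution. Collisions
(self-loops, duplicate edges) are redrawn; in the degenerate case of a
saturated neighbourhood the edge is left in place with a warning.

```{r transition}
sw <- ws_swp_sweep(n = 300, r = 5, p_grid = c(1e-3, 0.02, 0.5, 1),
                   n_seeds = 5, seed = 1)
sw[, c("p", "phi_mean", "delta_mean")]
```

Along the transition $\phi$ is unimodal — for $N = 1000$, $r = 5$ it peaks
near $p = 0.02$ (the acceptance script recomputes the full 50-seed sweep) —
and $\delta$ falls smoothly from $+1$ to $-1$, crossing 0 at the peak. For
generated families the anchors are the family's own endpoints
($C_{latt} = C_w(p=0)$, $L_{rand} = L_w(p=1)$, and correspondingly
$L_{latt}$, $C_{rand}$), which `ws_swp_sweep()` handles automatically.

## Mapping observed networks onto the model

For an empirical network the nulls must be built from the data itself, at the
observed density and weight distribution:

* `lattice_null()` ranks the observed weights in decreasing order and fills
  ring-distance shells in increasing distance order — the $N$ strongest
  weights are shuffled among the distance-1 slots, the next strongest among
  the distance-2 slots, and so on until all edges are placed. Exact shell
  capacities are used ($N$ per shell, $N/2$ at the antipodal distance of an
  even ring). Ties are broken by stable order and a seeded within-shell
  shuffle, so the construction is reproducible yet unbiased.
* `random_null()` scatters the observed weights uniformly over node pairs.
* `degree_preserving_null()` (binary networks) randomizes by double-edge
  swaps, preserving the degree sequence exactly — the conventional binary
  reference. The binary pipeline defaults to it; the weighted pipeline
  defaults to the weight-shuffling null; `random_model` overrides either.

Both weight-conserving nulls conserve node count, edge count and the exact
weight multiset — this is the property that makes $\phi$ density-robust.
Real networks carry no canonical 1-D layout; the default identity ordering
on a unit ring is a neutral choice, and because placement is by distance
shell rather than node identity the null statistics depend only weakly on
it. Measured coordinates can be supplied through `ordering` or a full
`distance_matrix`.

`swp()` wires everything together: observed statistics, `n_realizations`
null draws per model (default 10, reported with standard errors), deviations,
$\phi$, $\delta$, and the comparison index $\sigma$. Runs are deterministic
given the master seed (per-draw seeds are derived by fixed offsets).

```{r pipeline}
net <- weighted_watts_strogatz(200, 5, p = 0.03, seed = 42)
swp(net, n_realizations = 5, seed = 1)
```

The flag `is_small_world` applies the pragmatic reference threshold
$\phi_T = 0.6$ (overridable). The statistic is best read continuously: its
value lies in comparing gradations of small-world structure across networks,
not in the binary call.

## Benchmark families

Two standard weighted benchmark families validate the statistic, both on
$N = 1024$ nodes with directed intermediate matrices reduced by
`symmetrize_upper()` (only the strict upper triangle is kept):

* **Hierarchical modular networks** (`hierarchical_modular_network()`):
  fully connected base modules of $2^{sz\_cl}$ nodes; a pair whose lowest
  common block lies $m$ levels above the base is connected with probability
  $2^{-m}$ and, when connected, carries weight $2^{-m}$ (the weight equals
  the placement probability). The level indexing is anchored at the base
  module ($p = 1$), the unique reading that reproduces the family's expected
  densities analytically. Clustered at every scale, but cross-module weights
  decay geometrically, so weighted paths are long: *not* small-world.
* **Modular networks** (`modular_network()`): 16 fully connected modules of
  64 nodes (weight 1) plus a budget of random inter-module edges of weight
  0.5 — clustered *and* short-pathed: small-world at low and medium shortcut
  budgets, with $\phi$ declining as shortcuts erode module clustering.

```{r benchmarks}
network_density(hierarchical_modular_network(sz_cl = 5, seed = 1))
network_density(modular_network(65000, seed = 1))
```

The weighted SWP separates the two families cleanly at $\phi_T$ while the
small-world index $\sigma > 1$ classifies low/medium-density members of both
as small-world — the density inflation the SWP was designed to remove.

## Numerical and design notes

* **Representation.** Networks are dense symmetric double matrices (the
  regime of interest is $\le$ ~1000 nodes); an entry is an edge iff it is
  strictly positive, with no epsilon thresholding. Self-loops are stripped
  with a warning. Directed input is rejected unless upper-triangle
  symmetrization is requested explicitly.
* **Negative weights** (e.g. signed functional correlations) are rejected:
  the framework assumes nonnegative strengths. `normalize_weights()` offers
  optional max-rescaling to $[0, 1]$ for matrices on arbitrary scales, never
  applied implicitly.
* **Degenerate inputs.** Coinciding null anchors ($C_{latt} = C_{rand}$ or
  $L_{latt} = L_{rand}$) make the deviations undefined and raise an error
  rather than returning a clamped value; the $(0,0)$ deviation corner gets
  $\delta = 0$ by symmetry with a degeneracy flag.
* **Ordered vs unordered pairs.** $L$ averages ordered pairs; for symmetric
  networks the unordered average is identical, so the choice is
  unobservable.
* **Determinism.** Every stochastic operation takes an explicit seed and
  leaves the caller's RNG stream untouched; ensemble runners derive
  per-replicate seeds from the master seed by fixed offsets.
* **Problem sizes.** The shipped tests exercise the statistics against
  brute-force enumeration oracles at $n \le 8$, ensemble properties at
  $N = 1000$ with 5–50 realizations, and the benchmark families at full size
  ($N = 1024$, 10–20 seeds); the 50-realization Watts-Strogatz sweep matches
  the ensemble size used for the transition figures.

## What the generators do and do not emulate

The synthetic families capture the two ingredients the statistic is built
on — distance-dependent weights and density-matched nulls — but they are
idealisations: 1-D ring embeddings rather than 3-D anatomy, exact weight
conservation rather than measurement noise, and unimodal weight rules rather
than the heavy-tailed, thresholded, sometimes negative weights of empirical
connectomes. Passing the shipped checks therefore demonstrates correctness
of the statistics and generators, not that any particular empirical network
is small-world; for real data the choice of null layout (ring vs measured
distances) and of the clustering variant should be justified against the
physical meaning of the weights.

## Known limitations

* Directed networks, multigraphs and signed weights are out of scope.
* The lattice null's ring layout is a neutral default, not an anatomical
  model; supply measured distances where available.
* File import supports dense CSV/TSV matrices and 3-column edge lists;
  MATLAB `.mat` matrices must be exported to text first.
* $\sigma$ is provided for comparison only; it inherits all the defects that
  motivated the SWP.
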
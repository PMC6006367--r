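---
title: "Distributed trail maintenance and repair: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed trail maintenance and repair: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Arboreal turtle ants (*Cephalotes goniodontus*) forage exclusively on a
graph formed by the branches and vines of the forest canopy: junctions
are nodes, connecting branches are edges. The colony maintains a
routing backbone — a pheromone-marked trail linking nests — and when
wind or animal movement breaks a link, the ants must find and commit to
an alternative path using only local information. `antrail` implements
a family of biologically plausible distributed algorithms for this
problem, an agent-based engine to evaluate them, and the
maximum-likelihood machinery to fit their parameters to junction-choice
observations.

## The model

The environment is a weighted undirected graph $G = (V, E, W)$ whose
edge weights $w(v_1, v_2) \ge 0$ represent trail pheromone. Two nodes
are nests, joined by an initial path whose edges start with 10 units of
pheromone; all other edges start at 0. A repair scenario removes one
edge of that path.

Three parameters govern the dynamics:

* $q_{\mathrm{add}}$ — pheromone deposited per edge traversal. Fixed
  at 1; only the ratio to the initial charge matters.
* $q_{\mathrm{decay}} \in (0, 1)$ — per-time-step exponential decay:
  every weight is multiplied by $1 - q_{\mathrm{decay}}$ once per step.
  In the observational (maximum-likelihood) setting the same parameter
  acts per *second* of elapsed time.
* $q_{\mathrm{explore}} \in [0, 1]$ — the probability of an "explore
  step", a choice that would be impossible at
  $q_{\mathrm{explore}} = 0$.

### Edge-choice models

An ant at a node sees only the pheromone on adjacent edges, with the
edge back to its previously visited node excluded (one-step memory).
Three per-step laws are built in:

* **Weighted** (linear): with probability $q_{\mathrm{explore}}$ take a
  zero-pheromone edge uniformly at random; otherwise take a positive
  edge with probability proportional to its weight. If only one of the
  two classes exists it receives all the probability mass.
* **RankEdge** (non-linear): rank the distinct weight values in
  decreasing order. The top level is taken with probability
  $1 - q_{\mathrm{explore}}$ (uniformly within the level); each lower
  level is reached by "passing" all higher levels, so level $i$ carries
  mass $(1 - q_{\mathrm{explore}})\,q_{\mathrm{explore}}^{\,i-1}$, and
  the lowest level absorbs the remainder
  $q_{\mathrm{explore}}^{\,k-1}$.
* **Unweighted** (null): uniform over candidates, ignoring pheromone.
  It has no explore steps, because no choice depends on
  $q_{\mathrm{explore}}$.

Additional laws can be registered at run time
(`register_choice_model()`); the experiment drivers, metrics and MLE
all dispatch through the registry.

Weight ties (for ranking and for the zero/positive split) use exact
floating-point equality. Ties in this process arise from identical
deposit-and-decay histories, which produce bit-identical doubles; an
equality tolerance would invent ties the dynamics never produced.

A useful ordering fact, tested as a property: at any junction that
still offers an unexplored (zero-pheromone) candidate, RankEdge places
at least as much probability on a unique maximal edge as Weighted does
($1 - q$ versus $(1 - q)\, w_{\max} / \sum w$). Without a zero-weight
candidate the comparison can invert, because the linear law then
assigns the positive set its full mass.

### The synchronous engine

Each of $N$ ants carries four pieces of state: position, previous node,
destination nest, and a dead-end flag. One time-step proceeds:

1. Per node, ants queue first-in-first-out and **one ant departs per
   occupied node per step** (turtle ants walk narrow branches in single
   file). Departures are processed in canonical node order.
2. The departing ant's candidates exclude its previous node, with two
   exceptions: at a nest the arrival edge may be retaken (ants turn
   around there), and at a dead end (no candidate except the arrival
   edge) the ant backtracks, raises its dead-end flag, and deposits
   nothing until it reaches a node with at least two edges besides the
   one it just traversed, where the flag clears.
3. Choices are sampled from the configured law using the weights **as
   of the step's start**; deposits apply immediately. A non-explore
   move traverses the edge and deposits $q_{\mathrm{add}}$. An explore
   step traverses the edge and returns within the step, depositing
   $2 q_{\mathrm{add}}$ and leaving the position unchanged; the
   explored neighbour becomes the ant's one-step memory, since that is
   the edge it last walked.
4. After all departures, every weight decays once by
   $1 - q_{\mathrm{decay}}$. Any positive weight left bit-identical by
   the multiplication (underflow, near $10^{-300}$) is reset to exactly
   zero, so edges eventually become genuinely unexplored again.
5. An ant arriving at its destination nest records its *chosen path* —
   the cycle-free node sequence of the completed traversal — and turns
   around.

The engine literature leaves the within-step ordering of deposits and
decay open; depositing first and decaying once globally makes the total
pheromone obey the exact per-step identity
$W_{t+1} = (W_t + q_{\mathrm{add}} E_t + 2 q_{\mathrm{add}} X_t)(1 -
q_{\mathrm{decay}})$ (with $E_t$ ordinary deposits and $X_t$
explore-returns), which the test suite verifies to floating-point
rounding over full runs. Reading choice weights from the step-start
snapshot makes the step order-independent in distribution and keeps
runs reproducible.

Experiments place the ants uniformly at random on initial-path nodes
with random destinations (bi-directional search). The uni-directional
ablation places all ants on the `nest_u` side of the break, all seeking
`nest_v`; the backtracking ablation simply never excludes the previous
node. Defaults follow the study conditions: $N = 100$ ants, $T = 1000$
steps, 50 repeats, RankEdge at $q_{\mathrm{explore}} = 0.20$,
$q_{\mathrm{decay}} = 0.02$ and Weighted at $0.05, 0.01$ (the
field-estimated optima).

## Benchmark networks

Five scenarios of increasing complexity are generated
programmatically. Their published anchors — alternative-route counts,
optimal path lengths (12, 12, 10, 13, 13 nodes), the dead-end stub of
the Minimal graph, and the Spanning grid's property that every detour
must leave the trail before the break — fully constrain what the tests
check; the exact drawn geometries are not published, so the generators
are reconstructions satisfying those constraints:

* **Minimal** — a 10-node trail; the central break strands one trail
  node as a dead-end stub, and exactly one 12-node alternative exists.
* **Simple** — adds a second, disjoint 12-node detour.
* **Medium** — a shorter trail with six parallel 10-node alternatives
  and again a dead-end stub.
* **Full grid** — an 11×11 four-connected lattice whose middle row is
  the trail; the shortest alternative (13 nodes) steps one row off the
  break. No dead end exists, but the number of possible paths is
  enormous.
* **Spanning** — a sparse three-row lattice with vertical connectors
  only at columns 4 and 7, so no alternative can depart from the break
  nodes themselves (columns 5–6): ants must back up at least one node.

The break is always the middle edge of the trail (rounding toward
`nest_u` for even edge counts), matching the central breaks of the
published figures and keeping generation deterministic. Road-network
scenarios are sampled from a plain-text edge list by breadth-first
search from a random node until 121 nodes (the Full-grid size) are
visited; two random nodes become nests, one random shortest-path edge
is removed, and pairs whose removal disconnects them are redrawn.

## Performance metrics

All final-network metrics evaluate the ants' behaviour at
$q_{\mathrm{explore}} = 0$. A *solution path* is a nest-to-nest path
traversable with positive probability under that constraint: for
rank-type models, a *maximal path* (every step takes a maximum-weight
candidate, previous node excluded, within the positive-weight
subgraph); for the linear model, a *pheromone path* (any positive-weight
path); for the null model, any path.

* **Success** — at least one solution path exists (early-exit search).
* **Path entropy** — Shannon entropy (natural log, pinned by the
  published values $0.69 = \ln 2$ and $1.79 = \ln 6$) of the
  probability distribution over solution paths: tie branches contribute
  $1/|\text{tie}|$ per step for rank models, weight shares for the
  linear model, and a uniform distribution for the null model, each
  renormalized over completed simple paths. Entropy 0 means full
  consensus on one path.
* **Mean path length** — mean node count over solution paths.
* **Path elimination / path length pruning** — from the chosen-path
  log: the maximum over time of the entropy (resp. frequency-weighted
  mean length) of the cumulative chosen-path distribution, minus its
  final value. Both measure how much the colony narrows its portfolio
  of used routes during a run.
* **Robustness** — the geometric mean of success rates across
  networks, so one failing topology drags the score to zero.

Enumeration is restricted to simple paths of at most four times the
shortest alternative length, with a configurable cap (default $10^6$)
on enumerated states and paths; exceeding the cap raises a typed
condition rather than returning an approximation. The cap is reachable
for the linear model on dense grids — where the pheromone subgraph is
nearly the whole lattice — in which case the experiment drivers report
success (connectivity) but leave entropy as `NA`. Entropy and length
are averaged over successful repeats only, since no solution-path
distribution exists on failures.

## Maximum-likelihood estimation

Field-style observations record, per junction, the time of each ant's
choice and the edge taken. The likelihood replay starts each junction
at all-zero weights (nothing is known before the first observation),
decays weights by $(1 - q_{\mathrm{decay}})^{\Delta t}$ between
consecutive choices ($\Delta t$ in seconds), evaluates the model
probability of the chosen edge — excluding the arrival edge when the
arrival direction was recorded — and only then deposits one unit on the
chosen edge, so no choice is informed by its own deposit. Junction
log-likelihoods add.

`grid_search_mle()` sweeps a $(q_{\mathrm{explore}},
q_{\mathrm{decay}})$ grid (default $0.01, \dots, 0.99$ in steps of
0.01, matching the granularity at which the published optima are
reported). For the built-in models each choice's log-probability is
affine in $\log q_{\mathrm{explore}}$ and
$\log(1 - q_{\mathrm{explore}})$ at fixed weights, so one replay per
(junction, $q_{\mathrm{decay}}$) yields the entire
$q_{\mathrm{explore}}$ profile in closed form; the reference
implementation (`sequence_log_likelihood()`) is retained and the two
routes are cross-checked in the tests. Per-junction arg-maxes and
their across-junction standard deviations accompany the pooled
estimate; the parameter-free null model reports a constant surface and
`NA` estimates.

The synthetic generator (`generate_junction_sequence()`) runs the same
process forward with known parameters. Inter-arrival times default to
a fixed 5 s — a round value consistent with the reported observation
sessions (hundreds of choices over 7–24 minutes); the published record
does not include arrival statistics, so no empirical distribution is
fitted. Parameter recovery on such streams (13 junctions × 1000
choices recovers both parameters within one 0.01 grid step) substitutes
for the unavailable field dataset: the published per-junction
log-likelihood table cannot be reproduced without the original
recordings, but the machinery that would produce it is fully exercised.

## Numerical and design choices

* **Determinism** — every experiment draws per-repeat substreams from
  a master seed, so single repeats reproduce in isolation; generators
  accept explicit seeds; identical configuration and seed give
  bit-identical trajectories.
* **Queue details** — initial queue order is ant index; an explore
  traverse-and-return consumes its node's single departure for that
  step and re-queues the ant at the tail.
* **Ant placed on its destination nest** — its destination is flipped
  to the far nest, since searching for the nest one already occupies is
  vacuous.
* **Chosen-path logging** — only traversals that started at a nest are
  logged; the first leg of an ant placed mid-path has no well-defined
  origin nest.
* **Dead-end flag** — set only when the sole candidate is the arrival
  edge; with backtracking prevention disabled the candidate set is
  never empty and the flag never raises.
* **Underflow reset** — exact-zero reset after decay, rather than a
  detection-threshold parameter, keeps the model at two free
  parameters.

## Problem sizes and limitations

The package's own validation runs the full study conditions (100 ants,
1000 steps, 50 repeats) for the headline comparisons, and reduced sizes
(tens of ants, tens to hundreds of steps) for behavioural unit tests;
all are generated in code at test time.

The synthetic benchmarks are 2-D planar reconstructions with unit edge
lengths and single central breaks; canopy networks are 3-D, have
variable edge lengths and traversal difficulty, and break in more
varied ways, so passing these tests shows the algorithms behave as
published under the study's idealizations, not that they describe field
colonies beyond them. Rank-type models other than RankEdge (several
max-edge variants exist in the wider literature) are not implemented,
but the registry accepts third-party laws with the same contract.
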
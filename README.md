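# antrail

Agent-based simulation and analysis of how arboreal turtle ants
(*Cephalotes goniodontus*) maintain their foraging trail network and
route around broken links. Turtle ants travel only on the natural graph
formed by overlapping branches and vines; junctions are nodes, branches
are edges, and the colony's routing backbone is a pheromone-marked
nest-to-nest path on that graph. When a link breaks, the colony must
find an alternative path and converge on it using nothing but local
pheromone sensing and one step of memory per ant.

`antrail` is for researchers in collective behaviour and bio-inspired
distributed computing who want to simulate, measure, and fit this class
of algorithms:

* **Pheromone-weighted graphs** with deposit (`w ← w + q_add`, with
  `q_add = 1`) and exponential decay (`w ← w (1 − q_decay)`) dynamics.
* **Edge-choice models**: the linear *Weighted* walk (probability
  proportional to pheromone, explores zero-pheromone edges with
  probability `q_explore`), the non-linear *RankEdge* walk (take the
  top-ranked weight level with probability `1 − q_explore`, pass to the
  next level with probability `q_explore`), and the *Unweighted* null
  model — plus a registry for third-party laws.
* **A synchronous multi-ant engine** with per-node FIFO queueing,
  explore traverse-and-return, backtracking avoidance, and dead-end
  pheromone suppression, under bi-/uni-directional and
  backtracking-ablation variants.
* **Benchmark networks** (Minimal, Simple, Medium, Full grid, Spanning
  grid) plus BFS sampling of real road networks from edge lists.
* **Metrics**: success rate, path entropy (nats), mean path length,
  path elimination, path length pruning, and cross-network robustness
  (geometric mean).
* **Maximum-likelihood fitting** of `(q_explore, q_decay)` to
  timestamped junction-choice records by grid search, with per-second
  decay, and a synthetic generator of such records with known ground
  truth.

## Worked example

Repair a broken trail across the 11×11 grid with RankEdge at its
field-estimated parameters:

```r
library(antrail)

inst <- make_full_grid()          # 121 nodes, middle-row trail, central break
cfg  <- sim_config(q_explore = 0.20, q_decay = 0.02, model = "rankedge",
                   n_ants = 100, n_steps = 1000, n_repeats = 50, seed = 1)
ex <- run_repair_experiment(inst, cfg)
ex
#> <trail_experiment: model=rankedge q_explore=0.2 q_decay=0.02, 50 repeats>
#>   success rate: 0.80
#>   mean path entropy (successful): 0.000
#>   mean path length  (successful): 13.00
```

In this run the colony reconnected the nests in 80% of the repeats
(the published estimate for this setting is 70%, with a wide binomial
interval at 50 repeats). Whenever it succeeded it converged on a
*single* consensus path — path entropy 0 — of about 13 nodes, the
optimal detour length on this grid.

Fitting parameters back from synthetic junction observations:

```r
recs <- generate_junction_sequence(
  generator_spec("rankedge", q_explore = 0.2, q_decay = 0.02,
                 n_candidates = 4, n_choices = 1000, seed = 1))
fit <- grid_search_mle(recs, "rankedge",
                       q_explore_grid = seq(0.1, 0.3, 0.01),
                       q_decay_grid  = seq(0.01, 0.1, 0.01))
c(fit$q_explore, fit$q_decay)
#> [1] 0.20 0.02
```

A command-line front end (`inst/cli/antrail`) wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "antrail", package = "antrail"))')" \
    simulate --network full_grid --model rankedge \
    --q-explore 0.20 --q-decay 0.02 --out-dir results/
```

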
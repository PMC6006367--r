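#' Simulation configuration
#'
#' Bundles the behavioural parameters and experiment settings of the
#' synchronous multi-ant engine.  Defaults follow the study conditions:
#' 100 ants, 1000 time-steps, 50 repeat simulations, one unit of
#' pheromone deposited per traversal (`q_add = 1`, fixed), 10 units of
#' initial pheromone on each trail edge, bi-directional search and
#' backtracking avoidance enabled.
#'
#' @param q_explore exploration probability in \[0, 1\].
#' @param q_decay per-step pheromone decay rate in (0, 1).
#' @param model choice-model name (see [choice_models()]).
#' @param n_ants number of ants walking concurrently.
#' @param n_steps number of synchronous time-steps per run.
#' @param n_repeats number of repeat simulations per experiment.
#' @param seed master integer seed; per-repeat substreams are drawn from
#'   it so that each repeat is independently reproducible.
#' @param bidirectional if `FALSE`, all ants start on the `nest_u` side of
#'   the break and all walk in search of `nest_v` (uni-directional
#'   search); otherwise ants start anywhere on the initial path with
#'   random destinations.
#' @param prevent_backtracking if `FALSE`, the previously visited node is
#'   never excluded from the candidate set (ablation of the one-step
#'   memory).
#' @param q_add pheromone deposited per traversal; fixed at 1.
#' @return a `sim_config` list.
#' @export
sim_config <- function(q_explore, q_decay, model = "rankedge",
                       n_ants = 100L, n_steps = 1000L, n_repeats = 50L,
                       seed = 1L, bidirectional = TRUE,
                       prevent_backtracking = TRUE, q_add = 1) {
  if (q_add != 1) stop("q_add is fixed at 1")
  if (!(q_decay > 0 && q_decay < 1)) stop("q_decay must be in (0, 1)")
  if (q_explore < 0 || q_explore > 1) stop("q_explore must be in [0, 1]")
  if (n_ants < 1L || n_steps < 0L || n_repeats < 1L) {
    stop("n_ants/n_repeats must be >= 1 and n_steps >= 0")
  }
  choice_model(model)  # validate name early
  structure(list(q_explore = q_explore, q_decay = q_decay, model = model,
                 n_ants = as.integer(n_ants), n_steps = as.integer(n_steps),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 bidirectional = isTRUE(bidirectional),
                 prevent_backtracking = isTRUE(prevent_backtracking),
                 q_add = 1),
            class = "sim_config")
}

#' Deposit pheromone on an edge
#'
#' Adds `units` of pheromone to one edge (the per-traversal reinforcement
#' rule; an explore traverse-and-return leaves two units).
#'
#' @param g a [pheromone_graph()].
#' @param a,b node ids of the edge.
#' @param units amount to add (1 for a traversal, 2 for an explore
#'   traverse-and-return).
#' @return the updated graph.
#' @export
deposit <- function(g, a, b, units = 1) {
  i <- edge_index(g, a, b)
  if (i == 0L) stop("no such edge: ", a, " -- ", b)
  g$w[i] <- g$w[i] + units
  g
}

#' Decay all pheromone weights
#'
#' Multiplies every edge weight by `1 - q_decay`.  Any positive weight
#' left bit-identical by the multiplication (floating-point underflow,
#' around 1e-300) is reset to exactly 0, so that edges eventually become
#' genuinely unexplored again rather than holding a denormal remnant.
#'
#' @param g a [pheromone_graph()].
#' @param q_decay decay rate in (0, 1).
#' @return the updated graph.
#' @export
decay_all <- function(g, q_decay) {
  stopifnot(q_decay > 0, q_decay < 1)
  w_new <- g$w * (1 - q_decay)
  w_new[w_new == g$w & g$w > 0] <- 0
  g$w <- w_new
  g
}

# Fast in-engine probability law; must agree exactly with the registered
# probability functions (property-tested).
engine_probs <- function(model_id, model, wv, qe) {
  if (model_id == 3L) return(rep.int(1 / length(wv), length(wv)))
  if (model_id == 1L) {                     # weighted
    zero <- wv == 0
    if (all(zero)) return(rep.int(1 / length(wv), length(wv)))
    if (!any(zero)) return(wv / sum(wv))
    p <- numeric(length(wv))
    p[zero] <- qe / sum(zero)
    p[!zero] <- (1 - qe) * wv[!zero] / sum(wv[!zero])
    return(p)
  }
  if (model_id == 2L) {                     # rankedge
    levels <- sort(unique(wv), decreasing = TRUE)
    k <- length(levels)
    level_mass <- (1 - qe) * qe^(seq_len(k) - 1)
    level_mass[k] <- qe^(k - 1)
    lvl <- match(wv, levels)
    return(level_mass[lvl] / tabulate(lvl, k)[lvl])
  }
  unname(model$probabilities(
    list(candidates = seq_along(wv), weights = wv, q_explore = qe)))
}

#' Initialize a colony state
#'
#' Places `n_ants` ants uniformly at random on the nodes of the initial
#' path (or, for uni-directional search, on the `nest_u` side of the
#' break only), assigns each a random destination nest (or `nest_v` for
#' uni-directional search), and builds the mutable engine state.  Uses
#' the current RNG stream.
#'
#' @param instance a [network_instance()].
#' @param config a [sim_config()].
#' @return an environment of class `colony_state`.
#' @export
init_colony <- function(instance, config) {
  g <- instance$graph
  n <- length(g$nodes)
  N <- config$n_ants
  path_idx <- match(instance$initial_path, g$nodes)
  nest_idx <- match(c(instance$nest_u, instance$nest_v), g$nodes)
  if (config$bidirectional) {
    start_pool <- path_idx
  } else {
    if (is.null(instance$broken_edge)) {
      stop("uni-directional search requires a broken edge")
    }
    k <- match(instance$broken_edge[1L], instance$initial_path)
    k2 <- match(instance$broken_edge[2L], instance$initial_path)
    start_pool <- path_idx[seq_len(min(k, k2))]
  }
  pos <- start_pool[sample.int(length(start_pool), N, replace = TRUE)]
  dest <- if (config$bidirectional) {
    nest_idx[sample.int(2L, N, replace = TRUE)]
  } else {
    rep(nest_idx[2L], N)
  }
  # an ant assigned to the nest it already occupies seeks the other nest
  at_own <- pos == dest
  dest[at_own] <- nest_idx[1L] + nest_idx[2L] - dest[at_own]

  st <- new.env(parent = emptyenv())
  st$instance <- instance
  st$nodes <- g$nodes
  st$w <- g$w
  st$adj_ptr <- g$adj_ptr; st$adj_nbr <- g$adj_nbr; st$adj_eid <- g$adj_eid
  st$nest_idx <- nest_idx
  st$cfg <- config
  st$model <- choice_model(config$model)
  st$model_id <- match(config$model,
                       c("weighted", "rankedge", "unweighted"), nomatch = 0L)
  st$pos <- pos
  st$prev <- integer(N)                 # 0 = no previous node
  st$dest <- dest
  st$dead_end_flag <- logical(N)
  st$queue <- vector("list", n)
  st$qlen <- integer(n)
  # initial queue order is ant index
  for (a in seq_len(N)) {
    v <- pos[a]
    st$queue[[v]] <- c(st$queue[[v]], a)
    st$qlen[v] <- st$qlen[v] + 1L
  }
  st$walk <- matrix(0L, nrow = N, ncol = config$n_steps + 2L)
  st$walk[, 1L] <- pos
  st$walk_len <- rep(1L, N)
  st$walk_from_nest <- pos %in% nest_idx
  st$log_step <- integer(256L)
  st$log_path <- vector("list", 256L)
  st$log_n <- 0L
  st$step <- 0L
  # per-step ledger for the pheromone-conservation identity
  st$W_start <- numeric(config$n_steps)
  st$E_deposits <- integer(config$n_steps)
  st$X_explores <- integer(config$n_steps)
  st$W_end <- numeric(config$n_steps)
  class(st) <- c("colony_state", "environment")
  st
}

log_chosen_path <- function(st, step, path) {
  n <- st$log_n + 1L
  if (n > length(st$log_step)) {
    st$log_step <- c(st$log_step, integer(length(st$log_step)))
    st$log_path <- c(st$log_path, vector("list", length(st$log_path)))
  }
  st$log_step[n] <- step
  st$log_path[[n]] <- path
  st$log_n <- n
}

# Loop-erasure of an integer node sequence: scanning left to right, a
# revisit excises the intervening cycle.
erase_cycles_int <- function(v) {
  out <- integer(length(v))
  pos_of <- integer(max(v))
  len <- 0L
  for (x in v) {
    p <- pos_of[x]
    if (p > 0L && p <= len && out[p] == x) {
      len <- p
    } else {
      len <- len + 1L
      out[len] <- x
      pos_of[x] <- len
    }
  }
  out[seq_len(len)]
}

#' Advance the colony by one synchronous time-step
#'
#' Implements one step of the engine: per occupied node (in canonical
#' node order) the ant at the head of the FIFO queue departs, choosing
#' among candidate edges under the configured model with the previously
#' visited node excluded — except at a nest (where the arrival edge may
#' be re-taken) and at a dead end (where the ant backtracks, sets its
#' dead-end flag, and stops depositing until it reaches a node with at
#' least two other edges).  Edge choices are made against the weights as
#' of the step's start; deposits apply immediately; a single global decay
#' closes the step.  Explore steps traverse the chosen edge and return
#' within the step, leaving two units of pheromone.  An ant arriving at
#' its destination nest logs its cycle-free chosen path and turns around.
#'
#' @param st a `colony_state` from [init_colony()].
#' @return the state, invisibly (modified in place).
#' @export
advance_time_step <- function(st) {
  cfg <- st$cfg
  step <- st$step + 1L
  w0 <- st$w
  track <- step <= length(st$W_start)
  if (track) st$W_start[step] <- sum(w0)
  n_dep1 <- 0L
  n_dep2 <- 0L
  occupied <- which(st$qlen > 0L)
  heads <- vapply(occupied, function(v) st$queue[[v]][1L], integer(1L))
  for (i in seq_along(occupied)) {
    v <- occupied[i]
    ant <- heads[i]
    a <- st$adj_ptr[v]
    b <- st$adj_ptr[v + 1L] - 1L
    if (b < a) stop("ant ", ant, " is at an isolated node")
    nbrs <- st$adj_nbr[a:b]
    eids <- st$adj_eid[a:b]
    pv <- st$prev[ant]
    arrival_e <- 0L
    if (cfg$prevent_backtracking && pv > 0L && !(v %in% st$nest_idx)) {
      keep <- nbrs != pv
      if (!all(keep)) {
        arrival_e <- eids[!keep][1L]
        nbrs <- nbrs[keep]
        eids <- eids[keep]
      }
    }
    if (length(nbrs) == 0L) {
      # dead end: sole candidate was the arrival edge; backtrack without
      # depositing and raise the dead-end flag
      st$dead_end_flag[ant] <- TRUE
      move_ant(st, ant, v, pv, step)
      next
    }
    p <- engine_probs(st$model_id, st$model, w0[eids], cfg$q_explore)
    j <- if (length(p) == 1L) 1L else sample.int(length(p), 1L, prob = p)
    wv <- w0[eids]
    explore <- switch(st$model_id + 1L,
      st$model$is_explore(wv[j], wv),                 # registry model
      wv[j] == 0 && any(wv > 0),                      # weighted
      wv[j] < max(wv),                                # rankedge
      FALSE)                                          # unweighted
    if (explore) {
      # traverse and return within the step: two units, position kept,
      # but the explored edge becomes the ant's one-step memory
      if (!st$dead_end_flag[ant]) {
        st$w[eids[j]] <- st$w[eids[j]] + 2 * cfg$q_add
        n_dep2 <- n_dep2 + 1L
      }
      st$prev[ant] <- nbrs[j]
      q <- st$queue[[v]]
      st$queue[[v]] <- c(q[-1L], ant)
    } else {
      if (!st$dead_end_flag[ant]) {
        st$w[eids[j]] <- st$w[eids[j]] + cfg$q_add
        n_dep1 <- n_dep1 + 1L
      }
      move_ant(st, ant, v, nbrs[j], step)
    }
  }
  # single global decay, with underflow reset to exact zero
  w_dec <- st$w * (1 - cfg$q_decay)
  if (track) {
    st$E_deposits[step] <- n_dep1
    st$X_explores[step] <- n_dep2
    st$W_end[step] <- sum(w_dec)
  }
  w_dec[w_dec == st$w & st$w > 0] <- 0
  st$w <- w_dec
  st$step <- step
  invisible(st)
}

# Relocate `ant` from node `v` to adjacent node `u`; handles queues, walk
# bookkeeping, dead-end flag clearing, and nest arrival.
move_ant <- function(st, ant, v, u, step) {
  st$queue[[v]] <- st$queue[[v]][-1L]
  st$qlen[v] <- st$qlen[v] - 1L
  st$queue[[u]] <- c(st$queue[[u]], ant)
  st$qlen[u] <- st$qlen[u] + 1L
  st$pos[ant] <- u
  st$prev[ant] <- v
  wl <- st$walk_len[ant] + 1L
  st$walk[ant, wl] <- u
  st$walk_len[ant] <- wl
  if (st$dead_end_flag[ant]) {
    # deposits resume at the first node with >= 2 edges besides the one
    # just traversed, i.e. degree >= 3
    if (st$adj_ptr[u + 1L] - st$adj_ptr[u] >= 3L) {
      st$dead_end_flag[ant] <- FALSE
    }
  }
  if (u == st$dest[ant]) {
    if (st$walk_from_nest[ant]) {
      log_chosen_path(st, step,
                      erase_cycles_int(st$walk[ant, seq_len(wl)]))
    }
    st$dest[ant] <- st$nest_idx[1L] + st$nest_idx[2L] - u
    st$walk[ant, 1L] <- u
    st$walk_len[ant] <- 1L
    st$walk_from_nest[ant] <- TRUE
  }
  invisible(st)
}

#' Run a colony for many steps
#'
#' @param st a `colony_state`.
#' @param n_steps number of synchronous steps.
#' @return the state, invisibly.
#' @export
run_colony <- function(st, n_steps = st$cfg$n_steps) {
  for (i in seq_len(n_steps)) advance_time_step(st)
  invisible(st)
}

# Final pheromone graph of a run.
final_graph <- function(st) {
  g <- st$instance$graph
  g$w <- st$w
  g
}

# Chosen-path log of a run, as node-id sequences.
chosen_path_log <- function(st) {
  n <- st$log_n
  structure(
    list(step = st$log_step[seq_len(n)],
         path = lapply(st$log_path[seq_len(n)],
                       function(p) st$nodes[p])),
    class = "chosen_path_log")
}

#' Run a repair (or maintenance) experiment
#'
#' Runs `n_repeats` independent simulations of the configured colony on
#' fresh copies of the instance, and scores each final pheromone network:
#' success (a solution path exists), path entropy and mean solution-path
#' length (successful repeats only), and the two pruning measures derived
#' from the chosen-path log.  Per-repeat RNG substreams are drawn from
#' the master seed, so any repeat can be reproduced in isolation.
#'
#' @param instance a [network_instance()], or a function `(repeat_index)`
#'   returning one (for resampled scenarios).
#' @param config a [sim_config()].
#' @param path_metrics if `FALSE`, skip solution-path enumeration
#'   (entropy and mean length are `NA`); success is still computed, via
#'   an early-exit search.  Useful for the linear model on dense
#'   networks, where full enumeration exceeds the path cap.
#' @param keep_state if `TRUE`, retain each repeat's final `colony_state`
#'   (memory-heavy; default `FALSE`).
#' @param enumeration_cap passed to [enumerate_solution_paths()].
#' @return a `trail_experiment` object: list with `config` and `results`
#'   (data frame with one row per repeat: `repeat_`, `success`,
#'   `entropy`, `mean_length`, `elimination`, `pruning`), plus
#'   `final_graphs` and `logs`.
#' @export
run_repair_experiment <- function(instance, config, path_metrics = TRUE,
                                  keep_state = FALSE,
                                  enumeration_cap = 1e6) {
  factory <- if (is.function(instance)) instance else function(r) instance
  if (is.null(factory(1L)$broken_edge)) {
    stop("instance has no broken edge; use run_maintenance_experiment()")
  }
  run_experiment_engine(factory, config, path_metrics, keep_state,
                        enumeration_cap)
}

#' @rdname run_repair_experiment
#' @export
run_maintenance_experiment <- function(instance, config,
                                       path_metrics = TRUE,
                                       keep_state = FALSE,
                                       enumeration_cap = 1e6) {
  factory <- if (is.function(instance)) instance else function(r) instance
  if (!is.null(factory(1L)$broken_edge)) {
    stop("maintenance requires an intact instance (no broken edge)")
  }
  run_experiment_engine(factory, config, path_metrics, keep_state,
                        enumeration_cap)
}

run_experiment_engine <- function(factory, config, path_metrics,
                                  keep_state, enumeration_cap) {
  R <- config$n_repeats
  res <- data.frame(repeat_ = seq_len(R), success = NA,
                    entropy = NA_real_, mean_length = NA_real_,
                    elimination = NA_real_, pruning = NA_real_)
  graphs <- vector("list", R)
  logs <- vector("list", R)
  states <- if (keep_state) vector("list", R)
  substreams <- with_seed(config$seed,
                          sample.int(.Machine$integer.max - 1L, R))
  for (r in seq_len(R)) {
    inst <- factory(r)
    st <- with_seed(substreams[r], {
      s <- init_colony(inst, config)
      run_colony(s)
      s
    })
    g <- final_graph(st)
    inst_final <- inst
    inst_final$graph <- g
    res$success[r] <- success_indicator(inst_final, config$model)
    if (res$success[r] && path_metrics) {
      sp <- tryCatch(
        enumerate_solution_paths(inst_final, config$model,
                                 cap = enumeration_cap),
        antrail_cap_exceeded = function(e) NULL)
      if (!is.null(sp) && length(sp$paths) > 0L) {
        res$entropy[r] <- path_entropy(sp)
        res$mean_length[r] <- mean_path_length(sp)
      }
    }
    log <- chosen_path_log(st)
    if (length(log$step) > 0L) {
      res$elimination[r] <- path_elimination(log)
      res$pruning[r] <- path_length_pruning(log)
    }
    graphs[[r]] <- g
    logs[[r]] <- log
    if (keep_state) states[[r]] <- st
  }
  structure(list(config = config, results = res, final_graphs = graphs,
                 logs = logs, states = states),
            class = "trail_experiment")
}

#' @export
print.trail_experiment <- function(x, ...) {
  cat(sprintf(
    "<trail_experiment: model=%s q_explore=%.3g q_decay=%.3g, %d repeats>\n",
    x$config$model, x$config$q_explore, x$config$q_decay,
    nrow(x$results)))
  cat(sprintf("  success rate: %.2f\n", mean(x$results$success)))
  if (any(x$results$success & !is.na(x$results$entropy))) {
    ok <- x$results$success
    cat(sprintf("  mean path entropy (successful): %.3f\n",
                mean(x$results$entropy[ok], na.rm = TRUE)))
    cat(sprintf("  mean path length  (successful): %.2f\n",
                mean(x$results$mean_length[ok], na.rm = TRUE)))
  }
  invisible(x)
}

#' Pheromone-conservation ledger of a run
#'
#' Per-step record of total pheromone before deposits (`W_start`), unit
#' deposits (`E`), explore traverse-and-returns (`X`, two units each) and
#' total pheromone after decay but before underflow resets (`W_end`).
#' Satisfies `W_end = (W_start + q_add*E + 2*q_add*X) * (1 - q_decay)` up
#' to floating-point summation order.
#'
#' @param st a `colony_state` after running.
#' @return data frame with columns `step`, `W_start`, `E`, `X`, `W_end`.
#' @export
conservation_ledger <- function(st) {
  k <- st$step
  data.frame(step = seq_len(k), W_start = st$W_start[seq_len(k)],
             E = st$E_deposits[seq_len(k)], X = st$X_explores[seq_len(k)],
             W_end = st$W_end[seq_len(k)])
}
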
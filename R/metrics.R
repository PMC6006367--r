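#' Pheromone subgraph
#'
#' The subgraph induced by the two nests, every edge with positive
#' pheromone, and the endpoints of those edges.  This is the network a
#' non-exploring ant can perceive at the end of a run.
#'
#' @param instance a [network_instance()] (typically carrying a final
#'   pheromone graph).
#' @return a [pheromone_graph()].
#' @export
pheromone_subgraph <- function(instance) {
  g <- instance$graph
  keep <- which(g$w > 0)
  node_ids <- sort(unique(c(instance$nest_u, instance$nest_v,
                            g$nodes[g$edges[keep, , drop = FALSE]])))
  if (length(keep) == 0L) {
    return(build_adjacency(structure(
      list(nodes = node_ids,
           edges = matrix(integer(0), ncol = 2L), w = numeric(0)),
      class = "pheromone_graph")))
  }
  edges <- matrix(g$nodes[g$edges[keep, , drop = FALSE]], ncol = 2L)
  pheromone_graph(edges, weights = g$w[keep], nodes = node_ids)
}

cap_exceeded <- function(what, cap) {
  stop(structure(class = c("antrail_cap_exceeded", "error", "condition"),
                 list(message = sprintf(
                        "solution-path enumeration exceeded %s cap (%g)",
                        what, cap),
                      call = sys.call(-1L))))
}

#' Enumerate solution paths of a final network
#'
#' A *solution path* is a nest-to-nest path an ant can traverse with
#' positive probability at `q_explore = 0`.  For non-linear models
#' (RankEdge and other rank-type laws) these are the *maximal paths*:
#' every step takes an edge of maximum weight among the positive-weight
#' candidates, with the previous node excluded; ties branch, and each
#' branch carries probability `1/|tie set|`.  For the linear Weighted
#' model they are the *pheromone paths*: any simple nest-to-nest path
#' within the positive-weight subgraph, with probability given by the
#' product of weight shares.  For the Unweighted null model every simple
#' nest-to-nest path of the full graph is a solution path, with uniform
#' probability.
#'
#' Enumeration is restricted to simple paths of at most `max_len` nodes
#' (default four times the shortest nest-to-nest distance); probability
#' mass lost to dead-ending or cycling maximal walks is discarded and the
#' completed-path probabilities renormalized to a distribution.
#'
#' @param instance a [network_instance()].
#' @param model a model name (see [choice_models()]).
#' @param cap abort (condition class `antrail_cap_exceeded`) if more than
#'   this many paths complete or this many states are expanded.
#' @param max_len maximum path length in nodes.
#' @return an object of class `solution_paths`: list with `paths` (list
#'   of node-id vectors) and `prob` (numeric, sums to 1 when nonempty).
#' @export
enumerate_solution_paths <- function(instance, model, cap = 1e6,
                                     max_len = NULL) {
  mod <- choice_model(model)
  kind <- mod$solution
  g <- if (kind == "all") instance$graph else pheromone_subgraph(instance)
  src <- match(instance$nest_u, g$nodes)
  dst <- match(instance$nest_v, g$nodes)
  if (is.null(max_len)) {
    d <- tryCatch(shortest_alternative_length(instance), error = function(e) NA)
    max_len <- if (is.na(d)) length(g$nodes) else 4L * d
  }
  out <- new.env(parent = emptyenv())
  out$paths <- list()
  out$prob <- numeric(0)
  out$n <- 0L
  out$expansions <- 0L
  if (!is.na(src) && !is.na(dst)) {
    visited <- logical(length(g$nodes))
    visited[src] <- TRUE
    solution_dfs(g, src, 0L, dst, visited, src, 1, kind, max_len, cap, out)
  }
  p <- out$prob
  if (length(p) > 0L) p <- p / sum(p)
  if (kind == "all" && length(p) > 0L) p <- rep(1 / length(p), length(p))
  structure(list(paths = lapply(out$paths,
                                function(ix) g$nodes[ix]),
                 prob = p, model = mod$name),
            class = "solution_paths")
}

solution_dfs <- function(g, v, pv, dst, visited, path, prob, kind,
                         max_len, cap, out) {
  out$expansions <- out$expansions + 1L
  if (out$expansions > cap) cap_exceeded("state", cap)
  if (v == dst) {
    out$n <- out$n + 1L
    if (out$n > cap) cap_exceeded("path", cap)
    out$paths[[out$n]] <- path
    out$prob[out$n] <- prob
    return(invisible())
  }
  if (length(path) >= max_len) return(invisible())
  a <- g$adj_ptr[v]
  b <- g$adj_ptr[v + 1L] - 1L
  if (b < a) return(invisible())
  nbrs <- g$adj_nbr[a:b]
  eids <- g$adj_eid[a:b]
  if (pv > 0L) {
    keep <- nbrs != pv
    nbrs <- nbrs[keep]
    eids <- eids[keep]
  }
  if (length(nbrs) == 0L) return(invisible())
  wv <- g$w[eids]
  if (kind == "maximal") {
    tie <- wv == max(wv)
    nxt <- nbrs[tie]
    step_p <- rep(1 / sum(tie), sum(tie))
  } else if (kind == "pheromone") {
    nxt <- nbrs
    step_p <- wv / sum(wv)
  } else {                              # "all": every edge, equal shares
    nxt <- nbrs
    step_p <- rep(1 / length(nbrs), length(nbrs))
  }
  for (i in seq_along(nxt)) {
    u <- nxt[i]
    if (visited[u]) next                # non-simple continuations dropped
    visited[u] <- TRUE
    solution_dfs(g, u, v, dst, visited, c(path, u), prob * step_p[i],
                 kind, max_len, cap, out)
    visited[u] <- FALSE
  }
  invisible()
}

#' Success of a repair
#'
#' `success_indicator()` reports whether at least one solution path
#' exists in an instance's (final) graph under the given model, using an
#' early-exit search rather than full enumeration.  `success_rate()`
#' averages the indicator over the repeats of an experiment.
#'
#' @param instance a [network_instance()].
#' @param model a model name.
#' @return `success_indicator()`: logical scalar.
#' @export
success_indicator <- function(instance, model) {
  mod <- choice_model(model)
  if (mod$solution == "all") {
    g <- instance$graph
  } else {
    g <- pheromone_subgraph(instance)
  }
  src <- match(instance$nest_u, g$nodes)
  dst <- match(instance$nest_v, g$nodes)
  if (is.na(src) || is.na(dst)) return(FALSE)
  if (mod$solution %in% c("pheromone", "all")) {
    # any simple positive-weight path: plain connectivity (BFS)
    if (nrow(g$edges) == 0L) return(FALSE)
    seen <- logical(length(g$nodes))
    seen[src] <- TRUE
    frontier <- src
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        a <- g$adj_ptr[v]
        b <- g$adj_ptr[v + 1L] - 1L
        if (b < a) next
        for (u in g$adj_nbr[a:b]) {
          if (!seen[u]) {
            if (u == dst) return(TRUE)
            seen[u] <- TRUE
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    return(FALSE)
  }
  # maximal path existence: depth-first with early exit
  found <- new.env(parent = emptyenv())
  found$yes <- FALSE
  found$expansions <- 0L
  visited <- logical(length(g$nodes))
  visited[src] <- TRUE
  maximal_dfs_exists(g, src, 0L, dst, visited, found)
  found$yes
}

maximal_dfs_exists <- function(g, v, pv, dst, visited, found) {
  if (found$yes) return(invisible())
  found$expansions <- found$expansions + 1L
  if (found$expansions > 1e6) cap_exceeded("state", 1e6)
  if (v == dst) {
    found$yes <- TRUE
    return(invisible())
  }
  a <- g$adj_ptr[v]
  b <- g$adj_ptr[v + 1L] - 1L
  if (b < a) return(invisible())
  nbrs <- g$adj_nbr[a:b]
  eids <- g$adj_eid[a:b]
  if (pv > 0L) {
    keep <- nbrs != pv
    nbrs <- nbrs[keep]
    eids <- eids[keep]
  }
  if (length(nbrs) == 0L) return(invisible())
  wv <- g$w[eids]
  for (u in nbrs[wv == max(wv)]) {
    if (visited[u] || found$yes) next
    visited[u] <- TRUE
    maximal_dfs_exists(g, u, v, dst, visited, found)
    visited[u] <- FALSE
  }
  invisible()
}

#' @rdname success_indicator
#' @param x a `trail_experiment` or a logical vector of per-repeat
#'   outcomes.
#' @return `success_rate()`: fraction of repeats succeeding, in \[0, 1\].
#' @export
success_rate <- function(x) {
  if (inherits(x, "trail_experiment")) x <- x$results$success
  mean(as.logical(x))
}

#' Path entropy (nats)
#'
#' Shannon entropy, natural logarithm, of the probability distribution
#' over solution paths.  Zero means full consensus on a single path.
#'
#' @param solution_set a `solution_paths` object from
#'   [enumerate_solution_paths()].
#' @return nonnegative entropy in nats.
#' @export
path_entropy <- function(solution_set) {
  p <- solution_set$prob
  if (length(p) == 0L) stop("entropy undefined: no solution paths")
  -sum(p * log(p))
}

#' Mean solution-path length (nodes)
#'
#' @inheritParams path_entropy
#' @return unweighted mean node count over the solution paths.
#' @export
mean_path_length <- function(solution_set) {
  if (length(solution_set$paths) == 0L) {
    stop("path length undefined: no solution paths")
  }
  mean(lengths(solution_set$paths))
}

#' Remove cycles from a walk
#'
#' Left-to-right loop erasure: whenever a node already on the current
#' path is revisited, the intervening loop is excised.  The result is a
#' simple path with the same endpoints, which must be distinct.
#'
#' @param node_sequence vector of node ids.
#' @return simple node-id vector.
#' @export
remove_cycles <- function(node_sequence) {
  n <- length(node_sequence)
  if (n < 1L) stop("empty walk")
  if (node_sequence[1L] == node_sequence[n]) {
    stop("walk endpoints must be distinct")
  }
  ids <- unique(node_sequence)
  out <- erase_cycles_int(match(node_sequence, ids))
  ids[out]
}

# Shared scaffold of the two pruning measures: running value of a
# statistic over the cumulative chosen-path distribution, evaluated after
# each time-step that completes at least one traversal; returns max - final.
prune_measure <- function(log, stat) {
  n <- length(log$step)
  if (n == 0L) stop("chosen-path log is empty")
  ord <- order(log$step)
  keys <- vapply(log$path, paste, "", collapse = "\r")[ord]
  lens <- lengths(log$path)[ord]
  steps <- log$step[ord]
  ukeys <- unique(keys)
  idx <- match(keys, ukeys)
  counts <- integer(length(ukeys))
  total_len <- 0
  running_max <- -Inf
  value <- NA_real_
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && steps[j + 1L] == steps[i]) j <- j + 1L
    for (k in i:j) {
      counts[idx[k]] <- counts[idx[k]] + 1L
      total_len <- total_len + lens[k]
    }
    value <- stat(counts, total_len, j)
    if (value > running_max) running_max <- value
    i <- j + 1L
  }
  running_max - value
}

#' Pruning measures over the chosen-path log
#'
#' A *chosen path* is the cycle-free node sequence of one completed
#' nest-to-nest traversal.  Over a run the cumulative multiset of chosen
#' paths defines, at each time-step, an empirical distribution; the
#' *path elimination* is the maximum entropy of that distribution over
#' the run minus its final value, and the *path length pruning* is the
#' maximum frequency-weighted mean chosen-path length minus its final
#' value.  Both are nonnegative and zero when all traversals use one
#' path of constant length.
#'
#' @param log a `chosen_path_log` (component `logs` of a
#'   [run_repair_experiment()] result): list with `step` (completion
#'   times) and `path` (node-id vectors).
#' @return a nonnegative scalar.
#' @export
path_elimination <- function(log) {
  prune_measure(log, function(counts, total_len, n_done) {
    p <- counts[counts > 0L] / n_done
    -sum(p * log(p))
  })
}

#' @rdname path_elimination
#' @export
path_length_pruning <- function(log) {
  prune_measure(log, function(counts, total_len, n_done) {
    total_len / n_done
  })
}

#' Robustness across networks
#'
#' Geometric mean of success rates over a set of benchmark networks for
#' one parameter pair; zero whenever any single rate is zero, so the
#' measure rewards parameters that work everywhere.
#'
#' @param success_rates numeric vector of rates in \[0, 1\].
#' @return geometric mean in \[0, 1\].
#' @export
robustness <- function(success_rates) {
  if (length(success_rates) == 0L) stop("no success rates supplied")
  if (any(success_rates < 0)) stop("success rates must be nonnegative")
  if (any(success_rates == 0)) return(0)
  exp(mean(log(success_rates)))
}
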
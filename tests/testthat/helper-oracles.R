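# Brute-force oracles used across test files.

# Exhaustive enumeration of all q_explore = 0 walks of a model on an
# instance, independent of the package's solution-path DFS: expands every
# (node, previous) continuation using the registered probability
# functions directly, drops non-simple continuations, and renormalizes
# over walks that complete at nest_v.  Only feasible on tiny fixtures.
brute_force_solution_paths <- function(instance, model, max_len = 20L) {
  g <- instance$graph
  mod <- antrail::choice_model(model)
  if (mod$solution == "all") {
    gsub <- g
    keep <- seq_len(nrow(g$edges))
  } else {
    gsub <- antrail::pheromone_subgraph(instance)
    keep <- NULL
  }
  nodes <- gsub$nodes
  src <- match(instance$nest_u, nodes)
  dst <- match(instance$nest_v, nodes)
  paths <- list()
  probs <- numeric(0)
  recurse <- function(path, prob) {
    v <- path[length(path)]
    if (v == dst) {
      paths[[length(paths) + 1L]] <<- nodes[path]
      probs[length(probs) + 1L] <<- prob
      return(invisible())
    }
    if (length(path) >= max_len) return(invisible())
    a <- gsub$adj_ptr[v]
    b <- gsub$adj_ptr[v + 1L] - 1L
    if (b < a) return(invisible())
    nbrs <- gsub$adj_nbr[a:b]
    eids <- gsub$adj_eid[a:b]
    if (length(path) > 1L) {
      pv <- path[length(path) - 1L]
      nbrs_keep <- nbrs != pv
      nbrs <- nbrs[nbrs_keep]
      eids <- eids[nbrs_keep]
    }
    if (length(nbrs) == 0L) return(invisible())
    p <- mod$probabilities(antrail::choice_context(
      nbrs, gsub$w[eids], q_explore = 0))
    for (i in seq_along(nbrs)) {
      if (p[i] <= 0) next
      if (nbrs[i] %in% path) next        # non-simple: mass discarded
      recurse(c(path, nbrs[i]), prob * p[i])
    }
    invisible()
  }
  recurse(src, 1)
  if (length(probs)) probs <- probs / sum(probs)
  if (mod$solution == "all" && length(probs)) {
    probs <- rep(1 / length(probs), length(probs))
  }
  list(paths = paths, prob = probs)
}

# Canonical key for comparing path sets regardless of ordering.
path_set_table <- function(paths, prob) {
  keys <- vapply(paths, paste, "", collapse = ">")
  o <- order(keys)
  list(keys = keys[o], prob = prob[o])
}

# A tiny instance with a prescribed weight configuration.
weighted_fixture <- function(edges, weights, nest_u, nest_v, path) {
  inst <- antrail::network_instance(
    antrail::pheromone_graph(edges), nest_u, nest_v, path)
  inst$graph$w <- as.numeric(weights)[order_fixture_edges(inst, edges)]
  inst
}

# network_instance() canonicalizes edge order; map user-order weights in.
order_fixture_edges <- function(inst, edges) {
  g <- inst$graph
  key_g <- paste0(pmin(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]]), "|",
                  pmax(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]]))
  key_e <- paste0(pmin(edges[, 1], edges[, 2]), "|",
                  pmax(edges[, 1], edges[, 2]))
  match(key_g, key_e)
}
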
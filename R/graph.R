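#' Pheromone-weighted undirected graphs
#'
#' A `pheromone_graph` is an undirected graph whose edges carry a
#' nonnegative scalar weight, interpreted as the amount of trail pheromone
#' currently on the edge.  It is the shared environment that all simulated
#' ants read (when choosing an edge) and write (when depositing pheromone).
#'
#' Internally nodes are kept in a canonical (sorted) order and edges are
#' stored once per unordered pair, so `weight(a, b) == weight(b, a)` by
#' construction.  A compressed adjacency index is precomputed for fast
#' neighbourhood lookups in the simulation engine.
#'
#' @param edges two-column matrix or data frame of node ids (coerced to
#'   character), one undirected edge per row.  Duplicate rows and reversed
#'   duplicates are collapsed; self-loops are rejected.
#' @param weights numeric vector of initial pheromone weights, either
#'   length 1 (recycled) or one per (deduplicated) edge.  Default 0.
#' @param nodes optional character vector of node ids, to include isolated
#'   nodes beyond those incident to `edges`.
#' @return an object of class `pheromone_graph` with components `nodes`
#'   (character), `edges` (m x 2 integer matrix of node indices), and `w`
#'   (numeric pheromone per edge).
#' @export
pheromone_graph <- function(edges, weights = 0, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("`edges` must have two columns")
  mode(edges) <- "character"
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  node_ids <- sort(unique(c(as.character(nodes), edges[, 1L], edges[, 2L])))
  a <- match(edges[, 1L], node_ids)
  b <- match(edges[, 2L], node_ids)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste0(lo, "|", hi)
  keep <- !duplicated(key)
  if (length(weights) == 1L) weights <- rep(weights, sum(keep))
  else {
    if (length(weights) != length(key)) {
      stop("`weights` must be length 1 or one per edge")
    }
    weights <- weights[keep]
  }
  if (any(weights < 0)) stop("pheromone weights must be nonnegative")
  em <- cbind(lo[keep], hi[keep])
  ord <- order(em[, 1L], em[, 2L])
  g <- structure(
    list(nodes = node_ids,
         edges = matrix(as.integer(em[ord, , drop = FALSE]), ncol = 2L),
         w = as.numeric(weights[ord])),
    class = "pheromone_graph")
  build_adjacency(g)
}

# Compressed sparse adjacency: neighbours and incident-edge ids of node i
# are adj_nbr/adj_eid[adj_ptr[i]:(adj_ptr[i+1]-1)].
build_adjacency <- function(g) {
  n <- length(g$nodes)
  m <- nrow(g$edges)
  from <- c(g$edges[, 1L], g$edges[, 2L])
  to <- c(g$edges[, 2L], g$edges[, 1L])
  eid <- rep.int(seq_len(m), 2L)
  ord <- order(from, to)
  deg <- tabulate(from, nbins = n)
  g$adj_ptr <- c(1L, 1L + cumsum(deg))
  g$adj_nbr <- to[ord]
  g$adj_eid <- eid[ord]
  g$edge_key <- paste0(g$edges[, 1L], "|", g$edges[, 2L])
  g
}

#' @export
print.pheromone_graph <- function(x, ...) {
  cat(sprintf("<pheromone_graph: %d nodes, %d edges, total pheromone %.4g>\n",
              length(x$nodes), nrow(x$edges), sum(x$w)))
  invisible(x)
}

# Edge index of (a, b) given node ids or indices; 0 if absent.
edge_index <- function(g, a, b) {
  if (is.character(a)) a <- match(a, g$nodes)
  if (is.character(b)) b <- match(b, g$nodes)
  if (is.na(a) || is.na(b)) return(0L)
  key <- paste0(min(a, b), "|", max(a, b))
  i <- match(key, g$edge_key)
  if (is.na(i)) 0L else i
}

#' Edge weight lookup
#'
#' @param g a [pheromone_graph()].
#' @param a,b node ids (or integer node indices) of an edge.
#' @return the pheromone weight on edge (a, b).
#' @export
edge_weight <- function(g, a, b) {
  i <- edge_index(g, a, b)
  if (i == 0L) stop("no such edge: ", a, " -- ", b)
  g$w[i]
}

#' Set an edge weight
#'
#' Mostly useful for constructing test fixtures with prescribed pheromone
#' configurations.
#'
#' @inheritParams edge_weight
#' @param value new nonnegative weight.
#' @return the modified graph.
#' @export
set_edge_weight <- function(g, a, b, value) {
  stopifnot(value >= 0)
  i <- edge_index(g, a, b)
  if (i == 0L) stop("no such edge: ", a, " -- ", b)
  g$w[i] <- value
  g
}

# igraph view of a pheromone_graph (nodes carry their antrail index).
as_igraph <- function(g, edges = seq_len(nrow(g$edges))) {
  igraph::graph_from_edgelist(
    matrix(g$nodes[g$edges[edges, , drop = FALSE]], ncol = 2L),
    directed = FALSE)
}

#' Benchmark scenario: a graph, two nests, and an (optionally broken) path
#'
#' A `network_instance` bundles a [pheromone_graph()] with two nest nodes,
#' the initial nest-to-nest trail, and optionally a broken edge.  On
#' construction every surviving edge of the initial path is charged with
#' `initial_weight` units of pheromone (10 by default) and every other
#' edge with 0; the broken edge, when given, must lie on the initial path
#' and is removed from the graph.
#'
#' @param graph a [pheromone_graph()] describing the intact network.
#' @param nest_u,nest_v node ids of the two nests.
#' @param initial_path character vector of node ids: a simple path from
#'   `nest_u` to `nest_v` in `graph`.
#' @param broken_edge `NULL` (maintenance scenario) or a length-2 vector
#'   of node ids naming the initial-path edge to remove.
#' @param initial_weight pheromone charged on each surviving initial-path
#'   edge.
#' @return an object of class `network_instance`.
#' @export
network_instance <- function(graph, nest_u, nest_v, initial_path,
                             broken_edge = NULL, initial_weight = 10) {
  stopifnot(inherits(graph, "pheromone_graph"))
  nest_u <- as.character(nest_u)
  nest_v <- as.character(nest_v)
  initial_path <- as.character(initial_path)
  if (initial_path[1L] != nest_u ||
      initial_path[length(initial_path)] != nest_v) {
    stop("initial_path must run from nest_u to nest_v")
  }
  if (anyDuplicated(initial_path)) stop("initial_path must be simple")
  path_eids <- integer(length(initial_path) - 1L)
  for (i in seq_along(path_eids)) {
    e <- edge_index(graph, initial_path[i], initial_path[i + 1L])
    if (e == 0L) stop("initial_path step ", i, " is not a graph edge")
    path_eids[i] <- e
  }
  graph$w[] <- 0
  graph$w[path_eids] <- initial_weight
  if (!is.null(broken_edge)) {
    broken_edge <- as.character(broken_edge)
    be <- edge_index(graph, broken_edge[1L], broken_edge[2L])
    if (be == 0L || !(be %in% path_eids)) {
      stop("broken_edge must be an edge of the initial path")
    }
    keep <- setdiff(seq_len(nrow(graph$edges)), be)
    graph <- build_adjacency(structure(
      list(nodes = graph$nodes,
           edges = graph$edges[keep, , drop = FALSE],
           w = graph$w[keep]),
      class = "pheromone_graph"))
  }
  structure(
    list(graph = graph, nest_u = nest_u, nest_v = nest_v,
         initial_path = initial_path,
         broken_edge = if (is.null(broken_edge)) NULL else broken_edge),
    class = "network_instance")
}

#' @export
print.network_instance <- function(x, ...) {
  cat(sprintf(
    "<network_instance: %d nodes, %d edges, nests %s <-> %s, %s>\n",
    length(x$graph$nodes), nrow(x$graph$edges), x$nest_u, x$nest_v,
    if (is.null(x$broken_edge)) "intact"
    else paste0("broken edge ", x$broken_edge[1L], " -- ", x$broken_edge[2L])))
  invisible(x)
}

# Middle edge of a path (node-id vector), rounding toward the nest_u end
# when the edge count is even.
middle_path_edge <- function(path) {
  k <- length(path) - 1L
  i <- if (k %% 2L == 0L) k %/% 2L else (k + 1L) %/% 2L
  c(path[i], path[i + 1L])
}

rc <- function(r, c) sprintf("%02d,%02d", r, c)

lattice_edges <- function(rows, cols) {
  h <- do.call(rbind, lapply(rows, function(r) {
    if (length(cols) < 2L) return(NULL)
    cbind(rc(r, cols[-length(cols)]), rc(r, cols[-1L]))
  }))
  v <- do.call(rbind, lapply(cols, function(cc) {
    if (length(rows) < 2L) return(NULL)
    cbind(rc(rows[-length(rows)], cc), rc(rows[-1L], cc))
  }))
  rbind(h, v)
}

#' Benchmark networks
#'
#' Five benchmark scenarios of increasing topological complexity, each an
#' intact nest-to-nest trail (charged with 10 units of pheromone per edge)
#' plus a single induced break at the middle edge of the trail:
#'
#' * `make_minimal()` — the break leaves a dead-end stub on the trail and
#'   exactly one alternative route (12 nodes) exists.
#' * `make_simple()` — two alternative routes (both 12 nodes).
#' * `make_medium()` — six alternative routes (all 10 nodes), again with a
#'   dead-end stub.
#' * `make_full_grid()` — an 11x11 four-connected lattice (121 nodes, 220
#'   edges) whose middle row is the trail; shortest alternative 13 nodes.
#' * `make_spanning()` — a sparse three-row lattice in which every
#'   alternative route must leave the trail at least one node before the
#'   break; shortest alternative 13 nodes.
#'
#' The exact geometries are reconstructions constrained by the published
#' anchors (alternative-route counts, optimal path lengths, the dead-end
#' stub in Minimal, and the back-up-one-node property of Spanning); see
#' the methods vignette.
#'
#' @param broken if `FALSE`, return the intact network (maintenance
#'   scenario) instead of inducing the break.
#' @return a [network_instance()].
#' @export
make_full_grid <- function(broken = TRUE) {
  g <- pheromone_graph(lattice_edges(1:11, 1:11))
  path <- rc(6L, 1:11)
  network_instance(g, rc(6L, 1L), rc(6L, 11L), path,
                   broken_edge = if (broken) middle_path_edge(path))
}

#' @rdname make_full_grid
#' @export
make_minimal <- function(broken = TRUE) {
  edges <- rbind(
    cbind(rc(1L, 1:9), rc(1L, 2:10)),          # trail row
    cbind(rc(2L, 4:5), rc(2L, 5:6)),           # detour row
    c(rc(1L, 4L), rc(2L, 4L)),
    c(rc(1L, 6L), rc(2L, 6L)))
  path <- rc(1L, 1:10)
  network_instance(pheromone_graph(edges), rc(1L, 1L), rc(1L, 10L), path,
                   broken_edge = if (broken) middle_path_edge(path))
}

#' @rdname make_full_grid
#' @export
make_simple <- function(broken = TRUE) {
  edges <- rbind(
    cbind(rc(1L, 1:9), rc(1L, 2:10)),          # trail row
    cbind(rc(2L, 4:5), rc(2L, 5:6)),           # upper detour
    c(rc(1L, 4L), rc(2L, 4L)),
    c(rc(1L, 6L), rc(2L, 6L)),
    cbind(rc(0L, 3:6), rc(0L, 4:7)),           # lower detour
    c(rc(1L, 3L), rc(0L, 3L)),
    c(rc(0L, 7L), rc(1L, 7L)))
  path <- rc(1L, 1:10)
  network_instance(pheromone_graph(edges), rc(1L, 1L), rc(1L, 10L), path,
                   broken_edge = if (broken) middle_path_edge(path))
}

#' @rdname make_full_grid
#' @export
make_medium <- function(broken = TRUE) {
  detours <- do.call(rbind, lapply(2:7, function(r) {
    rbind(cbind(rc(r, 3:4), rc(r, 4:5)),
          c(rc(1L, 3L), rc(r, 3L)),
          c(rc(r, 5L), rc(1L, 5L)))
  }))
  edges <- rbind(cbind(rc(1L, 1:7), rc(1L, 2:8)), detours)
  path <- rc(1L, 1:8)
  network_instance(pheromone_graph(edges), rc(1L, 1L), rc(1L, 8L), path,
                   broken_edge = if (broken) middle_path_edge(path))
}

#' @rdname make_full_grid
#' @export
make_spanning <- function(broken = TRUE) {
  # horizontal edges of all three rows, vertical connectors only at
  # columns 4 and 7 (never adjacent to the break at columns 5-6)
  h <- do.call(rbind, lapply(5:7, function(r) cbind(rc(r, 1:10), rc(r, 2:11))))
  v <- rbind(cbind(rc(5L, c(4L, 7L)), rc(6L, c(4L, 7L))),
             cbind(rc(6L, c(4L, 7L)), rc(7L, c(4L, 7L))))
  path <- rc(6L, 1:11)
  network_instance(pheromone_graph(rbind(h, v)), rc(6L, 1L), rc(6L, 11L),
                   path, broken_edge = if (broken) middle_path_edge(path))
}

#' Shortest alternative path length
#'
#' Number of nodes on a shortest nest-to-nest path in the (possibly
#' broken) graph of an instance.  Path length follows the node-count
#' convention used throughout the package.
#'
#' @param instance a [network_instance()].
#' @return integer node count.
#' @export
shortest_alternative_length <- function(instance) {
  ig <- as_igraph(instance$graph)
  d <- igraph::distances(ig, v = instance$nest_u, to = instance$nest_v)[1L, 1L]
  if (!is.finite(d)) stop("nests are disconnected")
  as.integer(d) + 1L
}

#' Sample a scenario from a road network
#'
#' Samples a connected region of a (road) network by breadth-first search
#' from a random start node until `n_nodes` nodes are visited, then builds
#' a repair scenario on the induced subgraph: two random nodes become the
#' nests, their shortest path becomes the initial trail, and one random
#' edge of that path is removed.  If the removal disconnects the nests the
#' node pair is discarded and a fresh pair is drawn.
#'
#' @param edge_list two-column matrix/data frame of node ids (e.g. from
#'   [read_edge_list()]) describing a connected undirected graph.
#' @param n_nodes number of nodes to sample (121 matches the Full grid).
#' @param seed integer seed making the sample reproducible.
#' @param max_redraws how many nest pairs to try before giving up.
#' @return a [network_instance()].
#' @export
sample_road_network <- function(edge_list, n_nodes = 121L, seed = 1L,
                                max_redraws = 100L) {
  g0 <- pheromone_graph(edge_list)
  if (length(g0$nodes) < n_nodes) {
    stop("edge list has fewer than n_nodes nodes")
  }
  with_seed(seed, {
    ig0 <- as_igraph(g0)
    start <- sample(g0$nodes, 1L)
    bfs <- igraph::bfs(ig0, root = start, order = TRUE)
    visited <- igraph::V(ig0)$name[as.integer(bfs$order)[seq_len(n_nodes)]]
    if (anyNA(visited)) stop("graph is not connected: BFS exhausted")
    sub <- igraph::induced_subgraph(ig0, visited)
    el <- igraph::as_edgelist(sub)
    g <- pheromone_graph(el, nodes = visited)
    ig <- as_igraph(g)
    for (try in seq_len(max_redraws)) {
      nests <- sample(g$nodes, 2L)
      sp <- igraph::shortest_paths(ig, from = nests[1L], to = nests[2L])
      path <- igraph::V(ig)$name[as.integer(sp$vpath[[1L]])]
      if (length(path) < 2L) next   # disconnected pair
      i <- sample.int(length(path) - 1L, 1L)
      broken <- c(path[i], path[i + 1L])
      ig_cut <- igraph::delete_edges(
        ig, igraph::get_edge_ids(ig, broken))
      d <- igraph::distances(ig_cut, v = nests[1L], to = nests[2L])[1L, 1L]
      if (!is.finite(d)) next       # break disconnects the nests: redraw
      return(network_instance(g, nests[1L], nests[2L], path,
                              broken_edge = broken))
    }
    stop("no valid nest pair found after ", max_redraws, " redraws")
  })
}

#' Read / write plain-text edge lists
#'
#' Whitespace-separated node-id pairs, one undirected edge per line; `#`
#' starts a comment; duplicate edges collapse.
#'
#' @param path file path.
#' @return `read_edge_list()`: a two-column character matrix.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed edge-list line ", bad[1L])
  matrix(unlist(parts), ncol = 2L, byrow = TRUE)
}

#' @rdname read_edge_list
#' @param edges two-column matrix of node ids.
#' @export
write_edge_list <- function(edges, path) {
  writeLines(paste(edges[, 1L], edges[, 2L]), path)
  invisible(path)
}

#' Serialize / restore an instance as JSON
#'
#' @param instance a [network_instance()].
#' @param path file path.
#' @export
write_instance_json <- function(instance, path) {
  g <- instance$graph
  obj <- list(
    nodes = g$nodes,
    edges = matrix(g$nodes[g$edges], ncol = 2L),
    weights = g$w,
    nest_u = instance$nest_u, nest_v = instance$nest_v,
    initial_path = instance$initial_path,
    broken_edge = instance$broken_edge)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_instance_json
#' @export
read_instance_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # the break was already applied before serialization, so rebuild the
  # intact graph first and re-apply it
  edges <- rbind(matrix(as.character(obj$edges), ncol = 2L),
                 if (!is.null(obj$broken_edge)) as.character(obj$broken_edge))
  inst <- network_instance(
    pheromone_graph(edges, nodes = obj$nodes),
    obj$nest_u, obj$nest_v, obj$initial_path,
    broken_edge = obj$broken_edge)
  g <- inst$graph
  key <- paste0(g$nodes[g$edges[, 1L]], "|", g$nodes[g$edges[, 2L]])
  stored <- paste0(obj$edges[, 1L], "|", obj$edges[, 2L])
  stored_rev <- paste0(obj$edges[, 2L], "|", obj$edges[, 1L])
  idx <- match(key, stored)
  idx[is.na(idx)] <- match(key[is.na(idx)], stored_rev)
  inst$graph$w <- as.numeric(obj$weights)[idx]
  inst
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
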
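#' Synthetic junction-choice generator
#'
#' Simulates the observational process assumed by the junction
#' likelihood: ants arrive at a junction at intervals, pheromone decays
#' per second in between, each arrival samples an edge from the
#' configured choice model given the standing weights, and one unit of
#' pheromone is deposited on the chosen edge.  The ground-truth
#' parameters are known, so the generated streams exercise the full MLE
#' machinery without any field data.
#'
#' @param model choice-model name.
#' @param q_explore,q_decay generating parameter values (`q_decay` per
#'   second).
#' @param n_candidates number of candidate edges at the junction.
#' @param n_choices number of recorded choices (>= 1).
#' @param inter_arrival_s fixed inter-arrival time in seconds, or a
#'   function `(n) -> numeric` drawing the gaps.  The default 5 s sits
#'   within the cadence implied by observation sessions of a few hundred
#'   choices over 7-24 minutes.
#' @param seed integer seed.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(model, q_explore, q_decay, n_candidates = 4L,
                           n_choices = 100L, inter_arrival_s = 5,
                           seed = 1L) {
  choice_model(model)
  stopifnot(q_explore >= 0, q_explore <= 1, q_decay > 0, q_decay < 1,
            n_candidates >= 2L, n_choices >= 1L)
  if (!is.function(inter_arrival_s) && inter_arrival_s <= 0) {
    stop("inter_arrival_s must be positive")
  }
  structure(list(model = model, q_explore = q_explore, q_decay = q_decay,
                 n_candidates = as.integer(n_candidates),
                 n_choices = as.integer(n_choices),
                 inter_arrival_s = inter_arrival_s,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @param spec a [generator_spec()].
#' @param junction_id junction label for the generated records.
#' @return `generate_junction_sequence()`: a choice-record data frame
#'   (see [read_choice_records()]).
#' @export
generate_junction_sequence <- function(spec, junction_id = "j1") {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n <- spec$n_choices
    cand <- paste0("e", seq_len(spec$n_candidates))
    gaps <- if (is.function(spec$inter_arrival_s)) {
      spec$inter_arrival_s(n)
    } else {
      rep(spec$inter_arrival_s, n)
    }
    if (any(gaps < 0)) stop("negative inter-arrival time drawn")
    times <- cumsum(gaps)
    wts <- stats::setNames(numeric(length(cand)), cand)
    chosen <- character(n)
    t_last <- times[1L]
    for (i in seq_len(n)) {
      wts <- elapse(wts, times[i] - t_last, spec$q_decay)
      t_last <- times[i]
      draw <- sample_choice(
        choice_context(cand, unname(wts), spec$q_explore), spec$model)
      chosen[i] <- draw$choice
      wts[draw$choice] <- wts[draw$choice] + 1
    }
    data.frame(junction_id = junction_id, time_s = times,
               arrival = NA_character_, chosen = chosen,
               candidates = paste(cand, collapse = "|"),
               stringsAsFactors = FALSE)
  })
}

#' Small fixture networks for exact oracles
#'
#' Three hand-sized scenarios (at most 8 nodes) whose solution-path sets
#' can be enumerated exhaustively by brute force:
#'
#' * `chain` — a 5-node intact trail; exactly one solution path under
#'   every model.
#' * `diamond_stub` — a broken trail whose break leaves a one-node
#'   dead-end stub next to a single 4-node alternative route (a
#'   miniature of the Minimal benchmark).
#' * `double_diamond` — two parallel two-hop routes between the nests
#'   with exactly tied weights (5 units each), so maximal-path
#'   enumeration must split probability 1/2 : 1/2.
#'
#' @return named list of [network_instance()] objects.
#' @export
make_fixture_graphs <- function() {
  chain <- network_instance(
    pheromone_graph(cbind(c("u", "a", "b", "c"), c("a", "b", "c", "v"))),
    "u", "v", c("u", "a", "b", "c", "v"))
  diamond_stub <- network_instance(
    pheromone_graph(rbind(c("u", "a"), c("a", "b"), c("b", "v"),
                          c("a", "d"), c("d", "v"))),
    "u", "v", c("u", "a", "b", "v"), broken_edge = c("b", "v"))
  dd <- network_instance(
    pheromone_graph(rbind(c("u", "x1"), c("x1", "v"),
                          c("u", "x2"), c("x2", "v"))),
    "u", "v", c("u", "x1", "v"))
  dd$graph$w[] <- 5          # exact ties on all four edges
  list(chain = chain, diamond_stub = diamond_stub, double_diamond = dd)
}
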
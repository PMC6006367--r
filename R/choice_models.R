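#' Edge-choice context at a junction
#'
#' Everything an ant knows when it picks its next edge: the candidate
#' neighbours (with the pheromone weight of the connecting edges) and the
#' exploration probability.  The previously visited node, when one is to
#' be excluded, must be removed by the caller *before* constructing the
#' context — backtracking avoidance and its exceptions are enforced at a
#' single point in the simulator, not inside each model.
#'
#' @param candidates character (or integer) vector of candidate neighbour
#'   nodes; must be nonempty.
#' @param weights numeric vector of pheromone weights, one per candidate.
#' @param q_explore exploration probability in \[0, 1\].
#' @return an object of class `choice_context`.
#' @export
choice_context <- function(candidates, weights, q_explore) {
  if (length(candidates) == 0L) stop("no candidate edges")
  if (length(weights) != length(candidates)) {
    stop("one weight per candidate required")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (q_explore < 0 || q_explore > 1) stop("q_explore must be in [0, 1]")
  structure(list(candidates = candidates, weights = as.numeric(weights),
                 q_explore = q_explore),
            class = "choice_context")
}

#' Per-step edge-choice probabilities
#'
#' The three built-in per-step choice laws, each returning the exact
#' probability of moving to each candidate neighbour:
#'
#' * `weighted_probabilities()` — the linear law: with probability
#'   `q_explore` take an unexplored (zero-pheromone) edge uniformly;
#'   otherwise take a positive edge with probability proportional to its
#'   pheromone.  When only one of the two classes is present it receives
#'   all the mass.
#' * `rankedge_probabilities()` — the non-linear law: rank the distinct
#'   weight values in decreasing order; level *i* (1-based) receives mass
#'   `(1 - q_explore) * q_explore^(i-1)` split uniformly within the
#'   level, except the lowest level which absorbs the full remainder
#'   `q_explore^(k-1)`.  A single level receives mass 1.
#' * `unweighted_probabilities()` — the null law: uniform over candidates,
#'   ignoring pheromone.
#'
#' Weight equality (for ranking and for the zero/positive split) is exact
#' floating-point equality: ties arise from identical deposit/decay
#' histories, which produce identical doubles.
#'
#' @param ctx a [choice_context()].
#' @return named numeric vector of probabilities (names = candidates),
#'   summing to 1.
#' @export
weighted_probabilities <- function(ctx) {
  w <- ctx$weights
  q <- ctx$q_explore
  zero <- w == 0
  p <- numeric(length(w))
  if (all(zero)) {
    p[] <- 1 / length(w)
  } else if (!any(zero)) {
    p <- w / sum(w)
  } else {
    p[zero] <- q / sum(zero)
    p[!zero] <- (1 - q) * w[!zero] / sum(w[!zero])
  }
  stats::setNames(p, ctx$candidates)
}

#' @rdname weighted_probabilities
#' @export
rankedge_probabilities <- function(ctx) {
  w <- ctx$weights
  q <- ctx$q_explore
  levels <- sort(unique(w), decreasing = TRUE)
  k <- length(levels)
  level_mass <- (1 - q) * q^(seq_len(k) - 1)
  level_mass[k] <- q^(k - 1)        # lowest level absorbs the remainder
  lvl <- match(w, levels)
  p <- level_mass[lvl] / tabulate(lvl, k)[lvl]
  stats::setNames(p, ctx$candidates)
}

#' @rdname weighted_probabilities
#' @export
unweighted_probabilities <- function(ctx) {
  stats::setNames(rep(1 / length(ctx$weights), length(ctx$weights)),
                  ctx$candidates)
}

# ---- model registry ------------------------------------------------------

.models <- new.env(parent = emptyenv())

#' Choice-model registry
#'
#' Models are looked up by name so that experiments, the MLE machinery
#' and the command line can sweep over them.  A model is a probability
#' function with the [weighted_probabilities()] contract plus a predicate
#' `is_explore(chosen_weight, weights)` flagging choices that are
#' impossible at `q_explore = 0`, and a flag `linear` controlling which
#' solution-path notion applies (pheromone paths for linear models,
#' maximal paths otherwise).
#'
#' @param name model name, e.g. `"weighted"`, `"rankedge"`, `"unweighted"`.
#' @param probabilities probability function `(ctx) -> named numeric`.
#' @param is_explore function `(chosen_weight, weights) -> logical`.
#' @param linear logical.
#' @param solution which solution-path notion applies at `q_explore = 0`:
#'   `"maximal"` (follow maximum-weight edges; rank-type models),
#'   `"pheromone"` (any positive-weight path; linear models) or `"all"`
#'   (any path; the pheromone-blind null model).
#' @export
register_choice_model <- function(name, probabilities, is_explore,
                                  linear = FALSE,
                                  solution = if (linear) "pheromone"
                                             else "maximal") {
  solution <- match.arg(solution, c("maximal", "pheromone", "all"))
  assign(name, list(name = name, probabilities = probabilities,
                    is_explore = is_explore, linear = linear,
                    solution = solution),
         envir = .models)
  invisible(name)
}

#' @rdname register_choice_model
#' @export
choice_model <- function(name) {
  if (!exists(name, envir = .models, inherits = FALSE)) {
    stop("unknown choice model: ", name, " (registered: ",
         paste(sort(ls(.models)), collapse = ", "), ")")
  }
  get(name, envir = .models, inherits = FALSE)
}

#' @rdname register_choice_model
#' @export
choice_models <- function() sort(ls(.models))

register_builtin_models <- function() {
  register_choice_model(
    "weighted", weighted_probabilities,
    # a forced zero-weight choice (no positive edge present) can occur at
    # q_explore = 0, so it is not an explore step
    is_explore = function(chosen_w, w) chosen_w == 0 && any(w > 0),
    linear = TRUE)
  register_choice_model(
    "rankedge", rankedge_probabilities,
    is_explore = function(chosen_w, w) chosen_w < max(w),
    linear = FALSE)
  register_choice_model(
    "unweighted", unweighted_probabilities,
    is_explore = function(chosen_w, w) FALSE,
    linear = FALSE, solution = "all")
}

#' Sample one junction choice
#'
#' Draws a candidate from the model's exact distribution and flags
#' whether the draw was an explore step, i.e. a choice that could not
#' have occurred at `q_explore = 0`.
#'
#' @param ctx a [choice_context()].
#' @param model model name or object from [choice_model()].
#' @return list with `choice` (the candidate), `index`, and `explore`
#'   (logical).
#' @export
sample_choice <- function(ctx, model) {
  if (is.character(model)) model <- choice_model(model)
  p <- model$probabilities(ctx)
  i <- sample.int(length(p), 1L, prob = p)
  list(choice = ctx$candidates[i], index = i,
       explore = model$is_explore(ctx$weights[i], ctx$weights))
}
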
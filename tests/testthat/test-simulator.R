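test_that("deposit adds pheromone to exactly one edge", {
  g <- pheromone_graph(rbind(c("a", "b"), c("b", "c")), weights = c(3, 1))
  g2 <- deposit(g, "a", "b", 1)
  expect_equal(edge_weight(g2, "a", "b"), 4)
  expect_equal(edge_weight(g2, "b", "c"), 1)
  g3 <- deposit(g, "b", "c", 2)            # explore traverse-and-return
  expect_equal(edge_weight(g3, "b", "c"), 3)
  expect_error(deposit(g, "a", "c"), "no such edge")
})

test_that("decay_all scales every weight and resets underflow to zero", {
  g <- pheromone_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d")),
                       weights = c(10, 0, 1e-310))
  g2 <- decay_all(g, 0.02)
  expect_equal(edge_weight(g2, "a", "b"), 9.8)
  expect_equal(edge_weight(g2, "b", "c"), 0)
  # a denormal weight for which w * (1 - q) rounds back to w: reset to 0
  w <- 1e-310
  q <- 1e-17
  stopifnot(w * (1 - q) == w)              # construction of the example
  g3 <- decay_all(pheromone_graph(rbind(c("a", "b")), weights = w), q)
  expect_identical(edge_weight(g3, "a", "b"), 0)
})

test_that("engine probabilities agree exactly with the registry laws", {
  set.seed(5150)
  for (i in 1:100) {
    k <- sample(1:6, 1)
    w <- round(stats::rexp(k) * sample(c(0, 1), k, replace = TRUE), 4)
    q <- stats::runif(1)
    ctx <- choice_context(paste0("c", 1:k), w, q)
    expect_equal(antrail:::engine_probs(1L, NULL, w, q),
                 unname(weighted_probabilities(ctx)))
    expect_equal(antrail:::engine_probs(2L, NULL, w, q),
                 unname(rankedge_probabilities(ctx)))
    expect_equal(antrail:::engine_probs(3L, NULL, w, q),
                 unname(unweighted_probabilities(ctx)))
  }
})

# A deterministic corridor: chain with all trail pheromone ahead, so a
# rankedge ant at q_explore = 0 always advances.
chain_state <- function(q_explore = 0, q_decay = 0.02, n_ants = 1,
                        model = "rankedge", ...) {
  inst <- make_fixture_graphs()$chain
  cfg <- sim_config(q_explore, q_decay, model, n_ants = n_ants,
                    n_steps = 10L, n_repeats = 1L, ...)
  st <- init_colony(inst, cfg)
  list(inst = inst, cfg = cfg, st = st)
}

test_that("a non-explore move deposits then decays", {
  set.seed(1)
  x <- chain_state()
  st <- x$st
  # place the single ant at nest u deterministically
  st$pos[1] <- match("u", st$nodes)
  st$prev[1] <- 0L
  st$dest[1] <- match("v", st$nodes)
  st$queue <- vector("list", length(st$nodes))
  st$queue[[st$pos[1]]] <- 1L
  st$qlen[] <- 0L
  st$qlen[st$pos[1]] <- 1L
  w_ua <- edge_weight(antrail:::final_graph(st), "u", "a")
  advance_time_step(st)
  g <- antrail:::final_graph(st)
  expect_equal(st$nodes[st$pos[1]], "a")
  expect_equal(edge_weight(g, "u", "a"), (w_ua + 1) * 0.98)
})

test_that("dead-end return sets the flag and suppresses deposits", {
  inst <- make_fixture_graphs()$diamond_stub   # stub at b after break
  cfg <- sim_config(0, 0.02, "rankedge", n_ants = 1, n_steps = 1)
  set.seed(1)
  st <- init_colony(inst, cfg)
  b <- match("b", st$nodes); a <- match("a", st$nodes)
  st$pos[1] <- b; st$prev[1] <- a; st$dest[1] <- match("v", st$nodes)
  st$queue <- vector("list", length(st$nodes))
  st$queue[[b]] <- 1L
  st$qlen[] <- 0L; st$qlen[b] <- 1L
  w_ab <- edge_weight(antrail:::final_graph(st), "a", "b")
  w_tot <- sum(antrail:::final_graph(st)$w)
  advance_time_step(st)
  expect_equal(st$nodes[st$pos[1]], "a")
  # backtrack deposited nothing anywhere: all weights only decayed
  expect_equal(edge_weight(antrail:::final_graph(st), "a", "b"),
               w_ab * 0.98)
  expect_equal(sum(antrail:::final_graph(st)$w), w_tot * 0.98)
  # node a offers two edges besides the one just traversed (u and d), so
  # the dead-end state ends on arrival and the next move deposits again
  expect_false(st$dead_end_flag[1])
  w_before <- sum(antrail:::final_graph(st)$w)
  advance_time_step(st)
  expect_equal(sum(antrail:::final_graph(st)$w), (w_before + 1) * 0.98)
})

test_that("explore steps traverse and return, depositing two units", {
  # two candidates: trail edge (weight 10) and off-trail edge (0); with
  # q_explore high a rankedge ant eventually explores
  inst <- make_fixture_graphs()$diamond_stub
  cfg <- sim_config(0.99, 0.5, "rankedge", n_ants = 1, n_steps = 1)
  set.seed(42)
  st <- init_colony(inst, cfg)
  a <- match("a", st$nodes)
  st$pos[1] <- a; st$prev[1] <- match("u", st$nodes)
  st$dest[1] <- match("v", st$nodes)
  st$queue <- vector("list", length(st$nodes))
  st$queue[[a]] <- 1L
  st$qlen[] <- 0L; st$qlen[a] <- 1L
  # candidates at a (excluding u): b (w=10), d (w=0); P(explore d) = 0.99
  found <- FALSE
  for (i in 1:20) {
    pos0 <- st$pos[1]
    w_ad0 <- edge_weight(antrail:::final_graph(st), "a", "d")
    advance_time_step(st)
    if (st$nodes[st$pos[1]] == "a" && pos0 == a) {
      # explored: stayed at a, left two units on (a, d), remembers d
      expect_equal(edge_weight(antrail:::final_graph(st), "a", "d"),
                   (w_ad0 + 2) * 0.5)
      expect_equal(st$nodes[st$prev[1]], "d")
      found <- TRUE
      break
    }
    if (st$nodes[st$pos[1]] != "a") break
  }
  expect_true(found)
})

test_that("queued ants depart one per node per step, FIFO", {
  inst <- make_fixture_graphs()$chain
  cfg <- sim_config(0, 0.02, "rankedge", n_ants = 3, n_steps = 1)
  set.seed(9)
  st <- init_colony(inst, cfg)
  b <- match("b", st$nodes)
  st$pos[] <- b
  st$prev[] <- match("a", st$nodes)
  st$dest[] <- match("v", st$nodes)
  st$queue <- vector("list", length(st$nodes))
  st$queue[[b]] <- c(2L, 3L, 1L)           # arbitrary FIFO order
  st$qlen[] <- 0L; st$qlen[b] <- 3L
  advance_time_step(st)
  expect_equal(st$nodes[st$pos[2]], "c")   # head departed
  expect_equal(st$pos[c(1, 3)], c(b, b))   # others still queued, in order
  expect_equal(st$queue[[b]], c(3L, 1L))
  advance_time_step(st)
  expect_equal(st$nodes[st$pos[3]], "c")
  expect_equal(st$queue[[b]], 1L)
})

test_that("ants turn around at their destination nest", {
  set.seed(3)
  x <- chain_state()
  st <- x$st
  u <- match("u", st$nodes); v <- match("v", st$nodes)
  st$pos[1] <- match("c", st$nodes); st$prev[1] <- match("b", st$nodes)
  st$dest[1] <- v
  st$walk_len[1] <- 4L
  st$walk[1, 1:4] <- match(c("u", "a", "b", "c"), st$nodes)
  st$walk_from_nest[1] <- TRUE
  st$queue <- vector("list", length(st$nodes))
  st$queue[[st$pos[1]]] <- 1L
  st$qlen[] <- 0L; st$qlen[st$pos[1]] <- 1L
  advance_time_step(st)
  expect_equal(st$pos[1], v)
  expect_equal(st$dest[1], u)              # destination swapped
  log <- antrail:::chosen_path_log(st)
  expect_length(log$step, 1L)
  expect_equal(log$path[[1]], c("u", "a", "b", "c", "v"))
  # at the nest the arrival edge may be retaken: the sole candidate is c
  advance_time_step(st)
  expect_equal(st$nodes[st$pos[1]], "c")
})

test_that("pheromone conservation holds across a full run", {
  inst <- make_medium()
  cfg <- sim_config(0.2, 0.02, "rankedge", n_ants = 20, n_steps = 200,
                    n_repeats = 1)
  set.seed(8)
  st <- init_colony(inst, cfg)
  run_colony(st)
  led <- conservation_ledger(st)
  expect_equal(led$W_end,
               (led$W_start + led$E + 2 * led$X) * (1 - cfg$q_decay),
               tolerance = 1e-12)
  # and the ledger chains: next step starts from the decayed total
  # except where underflow resets removed residual mass
  expect_equal(led$W_start[-1], led$W_end[-nrow(led)], tolerance = 1e-9)
})

test_that("identical config and seed give bit-identical trajectories", {
  inst <- make_simple()
  cfg <- sim_config(0.2, 0.02, "rankedge", n_ants = 10, n_steps = 50,
                    n_repeats = 2, seed = 123)
  a <- run_repair_experiment(inst, cfg)
  b <- run_repair_experiment(inst, cfg)
  expect_identical(a$results, b$results)
  expect_identical(lapply(a$final_graphs, `[[`, "w"),
                   lapply(b$final_graphs, `[[`, "w"))
})

test_that("with q_explore = 0 and no break, rankedge holds the trail", {
  inst <- make_spanning(broken = FALSE)
  cfg <- sim_config(0, 0.01, "rankedge", n_ants = 20, n_steps = 100,
                    n_repeats = 1)
  set.seed(21)
  st <- init_colony(inst, cfg)
  run_colony(st)
  g <- antrail:::final_graph(st)
  on_path <- mapply(function(a, b) antrail:::edge_index(g, a, b),
                    inst$initial_path[-length(inst$initial_path)],
                    inst$initial_path[-1])
  off <- setdiff(seq_len(nrow(g$edges)), on_path)
  expect_true(all(g$w[off] == 0))
  expect_true(all(g$w[on_path] > 0))
})

test_that("ant count is conserved and moves are single edges", {
  inst <- make_medium()
  cfg <- sim_config(0.3, 0.05, "weighted", n_ants = 15, n_steps = 40,
                    n_repeats = 1)
  set.seed(14)
  st <- init_colony(inst, cfg)
  for (i in 1:40) {
    pos0 <- st$pos
    advance_time_step(st)
    expect_equal(sum(st$qlen), 15L)
    expect_length(st$pos, 15L)
    moved <- which(st$pos != pos0)
    for (a in moved) {
      expect_gt(antrail:::edge_index(st$instance$graph,
                                     pos0[a], st$pos[a]), 0L)
    }
  }
})

test_that("zero-step runs leave the graph unchanged", {
  inst <- make_minimal()
  cfg <- sim_config(0.2, 0.02, "rankedge", n_ants = 5, n_steps = 0,
                    n_repeats = 1)
  set.seed(2)
  st <- init_colony(inst, cfg)
  run_colony(st)
  expect_identical(antrail:::final_graph(st)$w, inst$graph$w)
})

test_that("experiment runners validate the scenario kind", {
  cfg <- sim_config(0.2, 0.02, "rankedge", n_ants = 2, n_steps = 1,
                    n_repeats = 1)
  expect_error(run_repair_experiment(make_minimal(broken = FALSE), cfg),
               "no broken edge")
  expect_error(run_maintenance_experiment(make_minimal(), cfg),
               "intact")
  expect_error(sim_config(0.2, 1.5, "rankedge"), "q_decay")
  expect_error(sim_config(-0.1, 0.5, "rankedge"), "q_explore")
  expect_error(sim_config(0.2, 0.5, "rankedge", q_add = 2), "q_add")
})
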
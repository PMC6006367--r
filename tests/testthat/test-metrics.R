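test_that("pheromone subgraph keeps nests, positive edges and endpoints", {
  fx <- make_fixture_graphs()$diamond_stub
  # all weights zero: two isolated nests
  z <- fx; z$graph$w[] <- 0
  sub0 <- pheromone_subgraph(z)
  expect_equal(sub0$nodes, c("u", "v"))
  expect_equal(nrow(sub0$edges), 0L)
  # intact trail at weight 10: the subgraph is that trail
  chain <- make_fixture_graphs()$chain
  sub1 <- pheromone_subgraph(chain)
  expect_setequal(sub1$nodes, c("u", "a", "b", "c", "v"))
  expect_equal(nrow(sub1$edges), 4L)
  # one weighted off-trail edge pulls in both its endpoints
  g <- fx
  g$graph <- set_edge_weight(g$graph, "a", "d", 1)
  g$graph$w[antrail:::edge_index(g$graph, "u", "a")] <- 0
  g$graph$w[antrail:::edge_index(g$graph, "a", "b")] <- 0
  sub2 <- pheromone_subgraph(g)
  expect_setequal(sub2$nodes, c("u", "v", "a", "d"))
})

test_that("solution paths match brute-force walk enumeration on fixtures", {
  fx <- make_fixture_graphs()
  # converged, tied, and asymmetric pheromone configurations
  cases <- list(
    list(inst = fx$chain, models = c("rankedge", "weighted", "unweighted")),
    list(inst = fx$double_diamond,
         models = c("rankedge", "weighted", "unweighted")),
    list(inst = {
      i <- fx$diamond_stub
      i$graph <- set_edge_weight(i$graph, "a", "d", 4)
      i$graph <- set_edge_weight(i$graph, "d", "v", 2)
      i
    }, models = c("rankedge", "weighted", "unweighted")),
    list(inst = {
      i <- fx$double_diamond
      i$graph <- set_edge_weight(i$graph, "u", "x1", 9)
      i
    }, models = c("rankedge", "weighted")))
  for (case in cases) {
    for (m in case$models) {
      got <- enumerate_solution_paths(case$inst, m)
      want <- brute_force_solution_paths(case$inst, m)
      g_tab <- path_set_table(got$paths, got$prob)
      w_tab <- path_set_table(want$paths, want$prob)
      expect_equal(g_tab$keys, w_tab$keys, info = m)
      expect_equal(g_tab$prob, w_tab$prob, tolerance = 1e-12, info = m)
    }
  }
})

test_that("tied maximal edges split probability equally", {
  dd <- make_fixture_graphs()$double_diamond
  sp <- enumerate_solution_paths(dd, "rankedge")
  expect_length(sp$paths, 2L)
  expect_equal(sp$prob, c(0.5, 0.5))
  expect_equal(path_entropy(sp), log(2))
})

test_that("rankedge on a converged chain yields one certain path", {
  chain <- make_fixture_graphs()$chain
  sp <- enumerate_solution_paths(chain, "rankedge")
  expect_length(sp$paths, 1L)
  expect_equal(sp$prob, 1)
  expect_equal(path_entropy(sp), 0)
  expect_equal(mean_path_length(sp), 5)
})

test_that("success indicator distinguishes the model families", {
  fx <- make_fixture_graphs()$diamond_stub
  # trail broken, alternative unexplored: no pheromone u -> v route
  expect_false(success_indicator(fx, "rankedge"))
  expect_false(success_indicator(fx, "weighted"))
  expect_true(success_indicator(fx, "unweighted"))  # topology suffices
  # charge the alternative: both families succeed
  fx$graph <- set_edge_weight(fx$graph, "a", "d", 1)
  fx$graph <- set_edge_weight(fx$graph, "d", "v", 1)
  expect_true(success_indicator(fx, "weighted"))
  # rankedge: maximal edge at a is still the stub edge (10 vs 1), and the
  # stub dead-ends, so no maximal path exists
  expect_false(success_indicator(fx, "rankedge"))
  fx$graph <- set_edge_weight(fx$graph, "a", "d", 11)
  expect_true(success_indicator(fx, "rankedge"))
  # all-zero weights fail for both pheromone-based families
  z <- make_fixture_graphs()$chain
  z$graph$w[] <- 0
  expect_false(success_indicator(z, "rankedge"))
  expect_false(success_indicator(z, "weighted"))
})

test_that("entropy follows the natural-log convention", {
  mk <- function(p) structure(list(paths = as.list(seq_along(p)), prob = p),
                              class = "solution_paths")
  expect_equal(path_entropy(mk(1)), 0)
  expect_equal(path_entropy(mk(rep(1 / 2, 2))), log(2))
  expect_equal(path_entropy(mk(rep(1 / 6, 6))), log(6))
  expect_error(path_entropy(mk(numeric(0))), "no solution paths")
})

test_that("mean path length averages node counts", {
  mk <- function(...) structure(list(paths = list(...),
                                     prob = rep(1, length(list(...)))),
                                class = "solution_paths")
  expect_equal(mean_path_length(mk(letters[1:13])), 13)
  expect_equal(mean_path_length(mk(letters[1:12], letters[1:14])), 13)
  expect_error(mean_path_length(mk()), "no solution paths")
})

test_that("remove_cycles performs left-to-right loop erasure", {
  expect_equal(remove_cycles(c("a", "b", "c", "b", "d")), c("a", "b", "d"))
  expect_equal(remove_cycles(c("a", "b", "c")), c("a", "b", "c"))
  expect_equal(remove_cycles(c("a", "b", "c", "d", "b", "e", "c", "f")),
               c("a", "b", "e", "c", "f"))
  expect_error(remove_cycles(c("a", "b", "a")), "distinct")
  # property: output is simple and a subsequence of the input
  set.seed(31)
  for (i in 1:30) {
    walk <- c("s", sample(letters[1:5], sample(3:12, 1), replace = TRUE), "t")
    out <- remove_cycles(walk)
    expect_false(anyDuplicated(out) > 0)
    expect_equal(out[1], "s")
    expect_equal(out[length(out)], "t")
    j <- 1L
    for (x in walk) if (j <= length(out) && x == out[j]) j <- j + 1L
    expect_equal(j, length(out) + 1L)       # subsequence check
  }
})

scripted_log <- function(steps, paths) {
  structure(list(step = steps, path = paths), class = "chosen_path_log")
}

test_that("pruning measures are zero for a single repeated path", {
  log <- scripted_log(1:5, rep(list(c("u", "a", "v")), 5))
  expect_equal(path_elimination(log), 0)
  expect_equal(path_length_pruning(log), 0)
})

test_that("path elimination tracks entropy loss of the cumulative mix", {
  pa <- c("u", "a", "v")
  pb <- c("u", "b", "c", "v")
  # equal use early, then only pa: S max at the 50/50 point, then falls
  log <- scripted_log(1:8, list(pa, pb, pa, pb, pa, pa, pa, pa))
  p_final <- c(6, 2) / 8
  expect_equal(path_elimination(log),
               log(2) - (-sum(p_final * log(p_final))))
  expect_gt(path_elimination(log), 0)
})

test_that("path length pruning tracks the running weighted mean", {
  p15 <- as.character(1:15)
  p13 <- as.character(101:113)
  log <- scripted_log(1:6, list(p15, p15, p13, p13, p13, p13))
  # running means: 15, 15, 14.33, 14, 13.8, 13.67; max 15
  L_final <- (2 * 15 + 4 * 13) / 6
  expect_equal(path_length_pruning(log), 15 - L_final)
})

test_that("ties within a time-step are evaluated after the whole step", {
  pa <- c("u", "a", "v")
  pb <- c("u", "b", "v")
  # both completions at step 1: the 50/50 mix is the *first* observable
  # state, so max entropy = final entropy = ln 2 and elimination is 0
  log <- scripted_log(c(1L, 1L), list(pa, pb))
  expect_equal(path_elimination(log), 0)
})

test_that("empty logs are rejected", {
  log <- scripted_log(integer(0), list())
  expect_error(path_elimination(log), "empty")
  expect_error(path_length_pruning(log), "empty")
})

test_that("robustness is the geometric mean, zero-dominated", {
  expect_equal(round(robustness(c(1, 0.98, 0.84, 0.7, 0.54, 0.7)), 2),
               0.78)
  expect_equal(robustness(rep(1, 6)), 1)
  expect_equal(robustness(c(1, 1, 0)), 0)
  expect_error(robustness(numeric(0)), "no success rates")
  set.seed(6)
  for (i in 1:20) {
    r <- stats::runif(sample(2:8, 1))
    expect_lte(robustness(r), mean(r) + 1e-12)
  }
})

test_that("enumeration caps raise a typed condition", {
  # dense weighted subgraph with a tiny cap
  full <- make_full_grid(broken = FALSE)
  full$graph$w[] <- 1
  expect_error(enumerate_solution_paths(full, "weighted", cap = 100),
               class = "antrail_cap_exceeded")
})
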
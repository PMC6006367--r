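#' Benchmark network lookup
#'
#' @param name one of `"minimal"`, `"simple"`, `"medium"`, `"full_grid"`,
#'   `"spanning"`.
#' @param broken induce the break (`TRUE`) or return the intact network.
#' @return a [network_instance()].
#' @export
benchmark_network <- function(name, broken = TRUE) {
  switch(match.arg(name,
                   c("minimal", "simple", "medium", "full_grid",
                     "spanning")),
         minimal = make_minimal(broken),
         simple = make_simple(broken),
         medium = make_medium(broken),
         full_grid = make_full_grid(broken),
         spanning = make_spanning(broken))
}

#' @rdname benchmark_network
#' @export
benchmark_networks <- function() {
  c("minimal", "simple", "medium", "full_grid", "spanning")
}

#' Run one simulation experiment and return tidy metrics
#'
#' Convenience wrapper around [run_repair_experiment()] /
#' [run_maintenance_experiment()] producing one tidy row per repeat,
#' suitable for binding across conditions.
#'
#' @param network a benchmark name (see [benchmark_network()]) or a
#'   [network_instance()].
#' @param model choice-model name.
#' @param q_explore,q_decay behavioural parameters.
#' @param broken simulate a repair (`TRUE`) or maintenance scenario.
#' @param path_metrics compute entropy/length per repeat (see
#'   [run_repair_experiment()]).
#' @param ... further [sim_config()] settings (`n_ants`, `n_steps`,
#'   `n_repeats`, `seed`, `bidirectional`, `prevent_backtracking`).
#' @return data frame with columns `network`, `model`, `q_explore`,
#'   `q_decay`, `repeat_`, `success`, `entropy`, `mean_length`,
#'   `elimination`, `pruning`.
#' @export
run_experiment <- function(network, model, q_explore, q_decay,
                           broken = TRUE, path_metrics = TRUE, ...) {
  if (inherits(network, "network_instance")) {
    inst <- network
    net_name <- "custom"
  } else {
    net_name <- network
    inst <- benchmark_network(network, broken = broken)
  }
  cfg <- sim_config(q_explore = q_explore, q_decay = q_decay,
                    model = model, ...)
  ex <- if (is.null(inst$broken_edge)) {
    run_maintenance_experiment(inst, cfg, path_metrics = path_metrics)
  } else {
    run_repair_experiment(inst, cfg, path_metrics = path_metrics)
  }
  cbind(data.frame(network = net_name, model = model,
                   q_explore = q_explore, q_decay = q_decay),
        ex$results)
}

#' Parameter sweep with cross-network robustness
#'
#' Runs every (`q_explore`, `q_decay`) grid combination on every listed
#' network and reports the per-network success rates together with their
#' geometric-mean robustness.
#'
#' @param networks character vector of benchmark names and/or a named
#'   list of [network_instance()] objects.
#' @param model choice-model name.
#' @param q_explore_grid,q_decay_grid numeric grids.
#' @param ... further [sim_config()] settings (typically a reduced
#'   `n_repeats` for exploratory sweeps).
#' @return data frame with one row per grid point: the grid values, one
#'   success-rate column per network, and `robustness`.
#' @export
parameter_sweep <- function(networks, model, q_explore_grid,
                            q_decay_grid, ...) {
  if (is.character(networks)) {
    networks <- stats::setNames(
      lapply(networks, benchmark_network), networks)
  }
  grid <- expand.grid(q_explore = q_explore_grid, q_decay = q_decay_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rates <- matrix(NA_real_, nrow(grid), length(networks),
                  dimnames = list(NULL, names(networks)))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(q_explore = grid$q_explore[i],
                      q_decay = grid$q_decay[i], model = model, ...)
    for (k in seq_along(networks)) {
      ex <- run_repair_experiment(networks[[k]], cfg,
                                  path_metrics = FALSE)
      rates[i, k] <- success_rate(ex)
    }
  }
  cbind(grid, as.data.frame(rates),
        robustness = apply(rates, 1L, robustness))
}

#' Model comparison report for junction-choice data
#'
#' Fits each requested model to the records by [grid_search_mle()] and
#' tabulates the estimates, their across-junction standard deviations,
#' and the pooled log-likelihood — one row per model, the parameter-free
#' null model reporting `NA` estimates.
#'
#' @param records a choice-record data frame.
#' @param models character vector of model names.
#' @param ... passed to [grid_search_mle()] (e.g. coarser grids).
#' @return data frame with columns `model`, `q_explore`,
#'   `sd_q_explore`, `q_decay`, `sd_q_decay`, `loglik`.
#' @export
mle_report <- function(records, models = c("unweighted", "weighted",
                                           "rankedge"), ...) {
  rows <- lapply(models, function(m) {
    fit <- grid_search_mle(records, m, ...)
    data.frame(model = m, q_explore = fit$q_explore,
               sd_q_explore = fit$sd_q_explore, q_decay = fit$q_decay,
               sd_q_decay = fit$sd_q_decay, loglik = fit$loglik)
  })
  do.call(rbind, rows)
}

#' Write experiment metrics as CSV
#'
#' Writes a tidy metrics table (from [run_experiment()] or
#' [parameter_sweep()]) with a schema-version header comment so that
#' downstream tooling can detect format changes.
#'
#' @param metrics data frame.
#' @param path output file.
#' @export
write_metrics_csv <- function(metrics, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# antrail metrics schema v1", con)
  utils::write.csv(metrics, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
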
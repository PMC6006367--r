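#' Junction choice records
#'
#' Observed junction decisions are kept in a plain data frame with one
#' row per choice: `junction_id`, `time_s` (seconds, non-decreasing
#' within a junction), `arrival` (the candidate leading back to the node
#' the ant arrived from, or `NA` when the arrival direction was not
#' recorded), `chosen` (the candidate taken) and `candidates` (all
#' candidate edges at the junction, pipe-separated).
#'
#' `read_choice_records()`/`write_choice_records()` use a tab-separated
#' file with exactly those columns.
#'
#' @param path file path.
#' @return a validated data frame of choice records.
#' @export
read_choice_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(junction_id = "character",
                                         time_s = "numeric",
                                         arrival = "character",
                                         chosen = "character",
                                         candidates = "character"))
  df$arrival[!nzchar(df$arrival) | is.na(df$arrival)] <- NA_character_
  validate_choice_records(df)
}

#' @rdname read_choice_records
#' @param records a choice-record data frame.
#' @export
write_choice_records <- function(records, path) {
  records <- validate_choice_records(records)
  records$arrival[is.na(records$arrival)] <- ""
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_choice_records
#' @export
validate_choice_records <- function(records) {
  need <- c("junction_id", "time_s", "arrival", "chosen", "candidates")
  if (!all(need %in% names(records))) {
    stop("choice records need columns: ", paste(need, collapse = ", "))
  }
  cand <- strsplit(records$candidates, "|", fixed = TRUE)
  ok <- mapply(function(ch, cs) ch %in% cs, records$chosen, cand)
  if (!all(ok)) {
    stop("chosen edge not among candidates at row ", which(!ok)[1L])
  }
  for (j in unique(records$junction_id)) {
    t <- records$time_s[records$junction_id == j]
    if (is.unsorted(t)) stop("times not non-decreasing at junction ", j)
  }
  records
}

#' Decay junction weights over elapsed time
#'
#' In the observational setting the decay parameter acts per second:
#' `dt` seconds of elapsed time multiply every weight by
#' `(1 - q_decay)^dt`.
#'
#' @param weights named numeric vector of per-candidate pheromone.
#' @param dt_seconds elapsed time, nonnegative.
#' @param q_decay decay rate per second, in (0, 1).
#' @return the decayed weights.
#' @export
elapse <- function(weights, dt_seconds, q_decay) {
  if (dt_seconds < 0) stop("elapsed time must be nonnegative")
  weights * (1 - q_decay)^dt_seconds
}

#' Log-likelihood of observed junction choices
#'
#' Replays each junction's record stream under a choice model: starting
#' from all-zero weights at the first observation, each record's weights
#' are decayed by the elapsed seconds, the model probability of the
#' chosen edge is accumulated (with the arrival edge excluded from the
#' candidates when recorded), and one unit of pheromone is then deposited
#' on the chosen edge — a choice is never informed by its own deposit.
#' Junctions contribute independently and their log-likelihoods add.
#'
#' @param records a choice-record data frame (see
#'   [read_choice_records()]).
#' @param model a model name (see [choice_models()]).
#' @param q_explore exploration probability.
#' @param q_decay decay rate per second.
#' @return total log-likelihood (<= 0).
#' @export
sequence_log_likelihood <- function(records, model, q_explore, q_decay) {
  records <- validate_choice_records(records)
  mod <- choice_model(model)
  total <- 0
  for (j in unique(records$junction_id)) {
    rj <- records[records$junction_id == j, , drop = FALSE]
    rj <- rj[order(rj$time_s), , drop = FALSE]
    wts <- numeric(0)
    t_last <- rj$time_s[1L]
    for (i in seq_len(nrow(rj))) {
      wts <- elapse(wts, rj$time_s[i] - t_last, q_decay)
      t_last <- rj$time_s[i]
      cand <- strsplit(rj$candidates[i], "|", fixed = TRUE)[[1L]]
      new <- setdiff(cand, names(wts))
      if (length(new)) wts[new] <- 0
      arr <- rj$arrival[i]
      use <- if (!is.na(arr)) setdiff(cand, arr) else cand
      if (!(rj$chosen[i] %in% use)) {
        stop("probability 0: chosen edge '", rj$chosen[i],
             "' excluded or absent at junction ", j,
             ", time ", rj$time_s[i])
      }
      p <- mod$probabilities(
        choice_context(use, unname(wts[use]), q_explore))
      pc <- p[[rj$chosen[i]]]
      if (pc <= 0) {
        stop("probability 0 for chosen edge '", rj$chosen[i],
             "' at junction ", j, ", time ", rj$time_s[i])
      }
      total <- total + log(pc)
      wts[rj$chosen[i]] <- wts[rj$chosen[i]] + 1
    }
  }
  total
}

# Integer-indexed preprocessing of one junction's records, so that the
# per-q_decay replay below touches no strings.
prep_junction <- function(rj) {
  cands <- strsplit(rj$candidates, "|", fixed = TRUE)
  ids <- unique(unlist(cands))
  recs <- vector("list", nrow(rj))
  t_prev <- rj$time_s[1L]
  for (i in seq_len(nrow(rj))) {
    cand_idx <- match(cands[[i]], ids)
    arr <- rj$arrival[i]
    use_idx <- if (!is.na(arr)) cand_idx[cands[[i]] != arr] else cand_idx
    chosen_idx <- match(rj$chosen[i], ids)
    if (!(chosen_idx %in% use_idx)) {
      stop("probability 0: chosen edge '", rj$chosen[i],
           "' excluded or absent at junction ", rj$junction_id[i],
           ", time ", rj$time_s[i])
    }
    recs[[i]] <- list(dt = rj$time_s[i] - t_prev, use = use_idx,
                      chosen = chosen_idx)
    t_prev <- rj$time_s[i]
  }
  list(n_ids = length(ids), recs = recs)
}

# Per-record sufficient statistics of the built-in likelihoods at a fixed
# q_decay: each choice contributes a * log(q_explore) +
# b * log(1 - q_explore) + const, so a junction's whole log-likelihood
# collapses to three accumulators and evaluates over the q_explore grid
# in closed form.
junction_loglik_coeffs <- function(prep, model_id, q_decay) {
  a <- 0; b <- 0; const <- 0
  wts <- numeric(prep$n_ids)
  fac <- 1 - q_decay
  for (rec in prep$recs) {
    if (rec$dt > 0) wts <- wts * fac^rec$dt
    wv <- wts[rec$use]
    wc <- wts[rec$chosen]
    if (model_id == 3L) {                       # unweighted
      const <- const - log(length(wv))
    } else if (model_id == 1L) {                # weighted
      zero <- wv == 0
      if (all(zero)) {
        const <- const - log(length(wv))
      } else if (wc == 0) {
        a <- a + 1
        const <- const - log(sum(zero))
      } else {
        if (any(zero)) b <- b + 1
        const <- const + log(wc / sum(wv[!zero]))
      }
    } else {                                    # rankedge
      levels <- sort(unique(wv), decreasing = TRUE)
      k <- length(levels)
      lvl <- match(wc, levels)
      m <- sum(wv == wc)
      a <- a + (lvl - 1)
      if (lvl < k) b <- b + 1
      const <- const - log(m)
    }
    wts[rec$chosen] <- wts[rec$chosen] + 1
  }
  c(a = a, b = b, const = const)
}

#' Grid-search maximum likelihood for (q_explore, q_decay)
#'
#' Evaluates the pooled log-likelihood of the observed junction choices
#' on a rectangular parameter grid and returns the arg-max, the full
#' surface, and per-junction estimates with across-junction standard
#' deviations.  For the built-in models the inner likelihood is computed
#' from per-junction sufficient statistics, so the grid sweep costs one
#' replay per (junction, `q_decay`) value; other registered models fall
#' back to direct evaluation at every grid point.
#'
#' @inheritParams sequence_log_likelihood
#' @param q_explore_grid,q_decay_grid increasing vectors of grid values
#'   inside (0, 1); the defaults cover 0.01 to 0.99 in steps of 0.01.
#' @return a `junction_mle` object: list with `model`, `q_explore`,
#'   `q_decay`, `loglik` (pooled maximum), `surface` (data frame
#'   `q_explore`, `q_decay`, `loglik`), `per_junction` (data frame of
#'   junction-level arg-maxes) and `sd_q_explore`/`sd_q_decay`.  For the
#'   parameter-free Unweighted model the estimates are `NA` and the
#'   surface is constant.
#' @export
grid_search_mle <- function(records, model,
                            q_explore_grid = seq(0.01, 0.99, by = 0.01),
                            q_decay_grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(q_explore_grid) == 0L || length(q_decay_grid) == 0L) {
    stop("empty parameter grid")
  }
  if (any(q_explore_grid <= 0 | q_explore_grid >= 1) ||
      any(q_decay_grid <= 0 | q_decay_grid >= 1)) {
    stop("grid values must lie strictly inside (0, 1)")
  }
  records <- validate_choice_records(records)
  if (nrow(records) == 0L) stop("no choice records supplied")
  mod <- choice_model(model)
  model_id <- match(model, c("weighted", "rankedge", "unweighted"),
                    nomatch = 0L)
  juncs <- unique(records$junction_id)
  nq <- length(q_explore_grid)
  nd <- length(q_decay_grid)
  log_qe <- log(q_explore_grid)
  log_1mqe <- log1p(-q_explore_grid)
  # loglik[qe, qd, junction]
  ll <- array(0, dim = c(nq, nd, length(juncs)))
  for (ji in seq_along(juncs)) {
    rj <- records[records$junction_id == juncs[ji], , drop = FALSE]
    rj <- rj[order(rj$time_s), , drop = FALSE]
    prep <- if (model_id > 0L) prep_junction(rj)
    for (di in seq_len(nd)) {
      if (model_id > 0L) {
        cf <- junction_loglik_coeffs(prep, model_id, q_decay_grid[di])
        ll[, di, ji] <- cf[["const"]] + cf[["a"]] * log_qe +
          cf[["b"]] * log_1mqe
      } else {
        for (qi in seq_len(nq)) {
          ll[qi, di, ji] <- sequence_log_likelihood(
            rj, model, q_explore_grid[qi], q_decay_grid[di])
        }
      }
    }
  }
  pooled <- apply(ll, c(1L, 2L), sum)
  param_free <- isTRUE(all.equal(max(pooled), min(pooled)))
  best <- arrayInd(which.max(pooled), dim(pooled))
  per <- data.frame(junction_id = juncs, q_explore = NA_real_,
                    q_decay = NA_real_, loglik = NA_real_)
  for (ji in seq_along(juncs)) {
    bi <- arrayInd(which.max(ll[, , ji]), c(nq, nd))
    per$q_explore[ji] <- q_explore_grid[bi[1L]]
    per$q_decay[ji] <- q_decay_grid[bi[2L]]
    per$loglik[ji] <- ll[bi[1L], bi[2L], ji]
  }
  structure(list(
    model = model,
    q_explore = if (param_free) NA_real_ else q_explore_grid[best[1L]],
    q_decay = if (param_free) NA_real_ else q_decay_grid[best[2L]],
    loglik = max(pooled),
    surface = data.frame(
      q_explore = rep(q_explore_grid, times = nd),
      q_decay = rep(q_decay_grid, each = nq),
      loglik = as.vector(pooled)),
    per_junction = if (param_free) {
      per$q_explore <- NA_real_; per$q_decay <- NA_real_; per
    } else per,
    sd_q_explore = if (param_free) NA_real_ else
      stats::sd(per$q_explore),
    sd_q_decay = if (param_free) NA_real_ else stats::sd(per$q_decay)),
    class = "junction_mle")
}

#' @export
print.junction_mle <- function(x, ...) {
  cat(sprintf("<junction_mle: model=%s>\n", x$model))
  if (is.na(x$q_explore)) {
    cat(sprintf("  q_explore = N/A, q_decay = N/A (parameter-free)\n"))
  } else {
    cat(sprintf("  q_explore = %.2f +/- %.2f\n", x$q_explore,
                x$sd_q_explore))
    cat(sprintf("  q_decay   = %.2f +/- %.2f\n", x$q_decay, x$sd_q_decay))
  }
  cat(sprintf("  pooled log-likelihood = %.2f\n", x$loglik))
  invisible(x)
}
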
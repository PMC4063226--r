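# Independent oracles used to cross-check the implementation: each is written
# directly from the defining formula or by brute force, sharing no code with
# the functions it checks.

# Workflow totals evaluated directly from the composition
# T = T_FR + T_1 + T_2 + T_FJ + T_R, reading the raw duration columns.
oracle_total_time <- function(w, mode) {
  b_steps <- list(c("build_index", "gene_align", "genome_align"),
                  c("junc_align", "span_reads"))
  pick <- function(col, s) {
    s <- intersect(s, names(col))
    if (length(s) == 0L) 0 else sum(col[s])
  }
  tmin <- function(tr) if (tr$negligible) 0 else tr$minutes
  if (mode == "serial") {
    col <- w$serial_steps
    pick(col, "filter_reads") + pick(col, b_steps[[1]]) + pick(col, b_steps[[2]]) +
      pick(col, "find_juncs") + pick(col, "report")
  } else {
    h <- w$host_steps
    r <- w$remote_steps
    t1 <- max(tmin(w$transfers[["1_in"]]) + pick(r, b_steps[[1]]) +
                tmin(w$transfers[["1_out"]]),
              pick(h, b_steps[[1]]))
    t2 <- max(tmin(w$transfers[["2_in"]]) + pick(r, b_steps[[2]]) +
                tmin(w$transfers[["2_out"]]),
              pick(h, b_steps[[2]]))
    pick(h, "filter_reads") + t1 + t2 + pick(h, "find_juncs") + pick(h, "report")
  }
}

# Pipeline makespan by longest-path relaxation over the explicit constraint
# DAG (precedence, instance exclusivity, buffer occupancy), iterated to a
# fixed point -- an independent formulation of the schedule.
oracle_makespan <- function(durations, n_buffers = 2L, remount = 0) {
  n <- nrow(durations)
  S <- ncol(durations)
  id <- function(j, s) (j - 1L) * S + s
  edges <- list()
  for (j in seq_len(n)) {
    for (s in seq_len(S)) {
      if (s > 1L) edges[[length(edges) + 1L]] <- c(id(j, s - 1L), id(j, s), remount)
      if (j > 1L) edges[[length(edges) + 1L]] <- c(id(j - 1L, s), id(j, s), 0)
      if (s < S && j > n_buffers)
        edges[[length(edges) + 1L]] <- c(id(j - n_buffers, s + 1L), id(j, s), 0)
    }
  }
  dur <- as.vector(t(durations))
  start <- rep(0, n * S)
  repeat {
    changed <- FALSE
    for (e in edges) {
      cand <- start[e[1]] + dur[e[1]] + e[3]
      if (cand > start[e[2]] + 1e-12) {
        start[e[2]] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  max(start + dur)
}

# Optimal max load over all assignments of weights to k groups (exact
# branch-and-bound enumeration; feasible for <= 10 items).
oracle_opt_maxload <- function(weights, k) {
  n <- length(weights)
  best <- Inf
  recurse <- function(i, loads) {
    if (i > n) {
      best <<- min(best, max(loads))
      return(invisible(NULL))
    }
    for (g in seq_len(k)) {
      loads[g] <- loads[g] + weights[i]
      if (max(loads) < best) recurse(i + 1L, loads)
      loads[g] <- loads[g] - weights[i]
    }
  }
  recurse(1L, numeric(k))
  best
}

# OLS coefficients from the normal equations, solved in closed form.
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(mean(y) - slope * mean(x), slope)  # (intercept, slope)
}

# Per-instance events must never overlap in time.
expect_hazard_free <- function(sim) {
  ev <- sim$events
  for (inst in unique(ev$instance_id)) {
    e <- ev[ev$instance_id == inst, ]
    e <- e[order(e$start_min), ]
    if (nrow(e) > 1L)
      expect_true(all(e$start_min[-1] >= e$end_min[-nrow(e)] - 1e-9),
                  label = paste("no overlap on", inst))
  }
  invisible(sim)
}

# No buffer may be mounted to two instances at the same simulated instant.
expect_buffer_exclusive <- function(sim) {
  ev <- sim$events
  bufs <- unique(unlist(strsplit(ev$buffers, ",", fixed = TRUE)))
  for (b in bufs[nzchar(bufs)]) {
    sel <- vapply(strsplit(ev$buffers, ",", fixed = TRUE),
                  function(x) b %in% x, logical(1))
    e <- ev[sel, ]
    e <- e[order(e$start_min, e$end_min), ]
    if (nrow(e) > 1L)
      expect_true(all(e$start_min[-1] >= e$end_min[-nrow(e)] - 1e-9),
                  label = paste("buffer", b, "mounted exclusively"))
  }
  invisible(sim)
}
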
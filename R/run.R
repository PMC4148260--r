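# Scenario engine: full runs, scheduled parameter changes, replicate
# sweeps and phase diagrams.

SCHEDULABLE <- c("C", "k", "C0", "r", "mode")

#' Scheduled parameter changes
#'
#' A schedule is a data frame with columns `t0` (step at which the change
#' takes effect), `param` and `value`. Only the punishment parameters
#' (`C`, `k`, `C0`, `mode`) and the flip rate `r` may be scheduled; `t0`
#' must be strictly increasing. Used e.g. to study the persistence of an
#' established norm after sanctioning efforts are reduced.
#'
#' @param t0 Integer vector of change points.
#' @param param Character vector of parameter names.
#' @param value List or vector of new values.
#' @return A validated schedule data frame.
#' @examples
#' schedule(1000, "C0", 0.25)
#' @export
schedule <- function(t0, param, value) {
  s <- data.frame(t0 = as.integer(t0), param = as.character(param))
  s$value <- as.list(value)
  validate_schedule(s)
  s
}

validate_schedule <- function(s) {
  if (is.null(s)) return(invisible(NULL))
  if (!all(c("t0", "param", "value") %in% names(s)))
    stop("a schedule needs columns t0, param, value")
  if (any(diff(s$t0) <= 0)) stop("schedule times t0 must be strictly increasing")
  bad <- setdiff(s$param, SCHEDULABLE)
  if (length(bad))
    stop("only punishment parameters and r can be scheduled; not: ",
         paste(bad, collapse = ", "))
  invisible(s)
}

apply_schedule_entry <- function(params, punish, param, value) {
  if (param == "r") {
    params$r <- as.numeric(value)
  } else if (param == "mode") {
    punish <- punishment_config(as.character(value), C = punish$C,
                                k = punish$k, C0 = punish$C0,
                                mutual = punish$mutual)
  } else {
    punish[[param]] <- as.numeric(value)
    punish$L <- (punish$k + 1) * punish$C
  }
  list(params = params, punish = punish)
}

#' Run a complete simulation
#'
#' Initializes the lattice from `params`, then advances it for `params$T`
#' steps (or until one behavior reaches `stop_share`, if given), applying
#' any scheduled parameter changes when their `t0` is reached. The run is
#' fully determined by `seed`.
#'
#' @param params A [sim_params()] object.
#' @param punish A [punishment_config()] object.
#' @param sched A [schedule()] data frame, or `NULL`.
#' @param seed Integer seed (defaults to `params$seed`).
#' @param metric Distance metric, see [neighborhood_offsets()].
#' @param record_events If `TRUE`, every sanction event is kept (time,
#'   punisher, punishee, sincere/hypocritical label, cost, fine).
#' @param stop_share If set (e.g. `0.8`), the run stops at the end of the
#'   first step in which either behavior is shown by at least this share
#'   of agents.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure R reference);
#'   both follow the identical update and RNG schedule and give
#'   bit-identical results for the same seed.
#' @return An object of class `norms_run`: a list with `timeseries` (one
#'   row per step: `t`, `share_b1`, `share_b2`, `share_preferred`,
#'   `mean_payoff`, `n_sanctions_sincere`, `n_sanctions_hypocritical`),
#'   the final `state`, `events`, `total_gross_payoff`, `stopped`,
#'   and the resolved `params`, `punish`, `seed`.
#' @examples
#' p <- sim_params(n_rows = 16, n_cols = 16, R = 2, T = 20)
#' run <- run_simulation(p, seed = 42)
#' tail(run$timeseries, 3)
#' @export
run_simulation <- function(params, punish = punishment_config("none"),
                           sched = NULL, seed = params$seed,
                           metric = c("chebyshev", "euclidean"),
                           record_events = FALSE, stop_share = NA,
                           engine = c("cpp", "r")) {
  metric <- match.arg(metric)
  engine <- match.arg(engine)
  validate_schedule(sched)
  if (!is.null(sched) && nrow(sched) &&
      (any(sched$t0 <= 0) || any(sched$t0 > params$T)))
    stop("schedule times must lie in (0, T]")
  set.seed(seed)
  state <- init_grid(params)
  off <- neighborhood_offsets(params$R, metric)

  breaks <- c(0L, if (!is.null(sched)) sched$t0, params$T)
  breaks <- breaks[!duplicated(breaks)]
  ts_list <- list(); ev_list <- list()
  total_gross <- 0; stopped <- FALSE

  for (seg in seq_len(length(breaks) - 1L)) {
    if (!is.null(sched)) {
      due <- which(sched$t0 == breaks[seg])
      for (i in due) {
        upd <- apply_schedule_entry(params, punish, sched$param[i],
                                    sched$value[[i]])
        params <- upd$params; punish <- upd$punish
      }
    }
    n_steps <- breaks[seg + 1L] - breaks[seg]
    if (engine == "cpp") {
      res <- engine_run(as.integer(state$preference),
                        as.integer(state$behavior),
                        as.numeric(state$last_payoff),
                        as.numeric(state$cumulative_payoff),
                        params$n_rows, params$n_cols, state$t, n_steps,
                        params$A, params$B, params$r, off,
                        punish_mode_code(punish), punish$C, punish$k,
                        punish$C0, punish$mutual, record_events,
                        if (is.na(stop_share)) -1 else stop_share)
      state$behavior <- matrix(res$behavior, params$n_rows, params$n_cols)
      state$last_payoff <- matrix(res$last_payoff, params$n_rows,
                                  params$n_cols)
      state$cumulative_payoff <- matrix(res$cumulative_payoff,
                                        params$n_rows, params$n_cols)
      state$t <- res$t
      ts_list[[seg]] <- as.data.frame(res$metrics)
      ev_list[[seg]] <- as.data.frame(res$events)
      total_gross <- total_gross + res$total_gross_payoff
      if (res$stopped) { stopped <- TRUE; break }
    } else {
      rows <- list(); evs <- list()
      for (i in seq_len(n_steps)) {
        out <- advance_step(state, params, punish, metric, record_events)
        state <- out$state
        rows[[i]] <- out$metrics
        evs[[i]] <- out$events
        total_gross <- total_gross + out$total_gross_payoff
        if (!is.na(stop_share)) {
          s1 <- out$metrics$share_b1
          if (s1 >= stop_share || 1 - s1 >= stop_share) {
            stopped <- TRUE; break
          }
        }
      }
      ts_list[[seg]] <- do.call(rbind, rows)
      ev_list[[seg]] <- do.call(rbind, evs)
      if (stopped) break
    }
  }

  ts <- do.call(rbind, ts_list)
  if (!is.null(ts) && nrow(ts))
    ts <- data.frame(t = ts$t, share_b1 = ts$share_b1,
                     share_b2 = 1 - ts$share_b1,
                     share_preferred = ts$share_preferred,
                     mean_payoff = ts$mean_payoff,
                     n_sanctions_sincere = ts$n_sanctions_sincere,
                     n_sanctions_hypocritical = ts$n_sanctions_hypocritical)
  events <- do.call(rbind, ev_list)
  if (!is.null(events) && nrow(events)) {
    events$mode <- punish$mode
    events$label <- ifelse(events$hypocritical == 1, "hypocritical",
                           "sincere")
  }
  structure(list(timeseries = ts, state = state, events = events,
                 total_gross_payoff = total_gross, stopped = stopped,
                 params = params, punish = punish, seed = seed,
                 metric = metric),
            class = "norms_run")
}

#' @export
print.norms_run <- function(x, ...) {
  cat(sprintf("norms_run: %d steps on %d x %d torus (seed %d)\n",
              x$state$t, x$params$n_rows, x$params$n_cols, x$seed))
  sh <- grid_shares(x$state)
  cat(sprintf("  final shares: b1 = %.3f, b2 = %.3f, preferred = %.3f\n",
              sh[1], sh[2], sh[3]))
  cat(sprintf("  outcome: %s\n", classify_outcome(x$state)))
  invisible(x)
}

#' Trajectory plot of a run
#'
#' @param x A `norms_run`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.norms_run <- function(x, ...) {
  ts <- x$timeseries
  graphics::matplot(ts$t, cbind(ts$share_b1, ts$share_preferred),
                    type = "l", lty = 1, col = c("black", "grey50"),
                    xlab = "t", ylab = "share", ylim = c(0, 1), ...)
  graphics::legend("bottomleft",
                   legend = c("showing behavior 1", "showing preferred"),
                   lty = 1, col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Deterministic seed for a sweep cell replicate
#'
#' Mixes a base seed with cell indices and a replicate index into a
#' 31-bit seed so that sweeps are reproducible and cells independent.
#'
#' @param base Base integer seed.
#' @param ... Further integer indices (cell coordinates, replicate).
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(base, ...) {
  x <- as.double(base) %% 2147483647
  for (i in c(...)) {
    x <- (x * 48271 + as.double(i) * 1009 + 12345) %% 2147483647
  }
  as.integer(x) + 1L
}

set_swept_param <- function(params, punish, name, value) {
  if (name %in% c("A", "B", "S", "p1", "p2", "r")) {
    params[[name]] <- value
  } else if (name %in% c("R", "T")) {
    params[[name]] <- as.integer(value)
  } else if (name == "BA") {
    params$B <- value * params$A
  } else if (name == "L") {
    punish$C <- value / (punish$k + 1)
    punish$L <- value
  } else if (name %in% c("C", "k", "C0")) {
    punish[[name]] <- value
    punish$L <- (punish$k + 1) * punish$C
  } else if (name == "mode") {
    punish <- punishment_config(value, C = punish$C, k = punish$k,
                                C0 = punish$C0, mutual = punish$mutual)
  } else {
    stop("unknown sweep parameter: ", name)
  }
  list(params = params, punish = punish)
}

#' Phase-diagram sweep
#'
#' Runs replicated simulations over a one- or two-dimensional grid of
#' parameter values and classifies each run with [classify_outcome()].
#' Axis parameters may be any of `A`, `B`, `S`, `p1`, `p2`, `r`, `R`,
#' `T`, `BA` (sets `B = BA * A`), `C`, `k`, `C0`, `mode`, or `L` (sets
#' `C = L / (k + 1)` at fixed `k`). Replicate seeds are derived
#' deterministically from `seed` and the cell indices.
#'
#' @param params Base [sim_params()].
#' @param punish Base [punishment_config()].
#' @param axis1,axis2 Lists `list(param = <name>, values = <vector>)`;
#'   `axis2` may be `NULL`.
#' @param replicates Independent runs per cell.
#' @param seed Base seed.
#' @param norm_threshold,coexist_threshold Passed to [classify_outcome()].
#' @param ... Passed to [run_simulation()] (e.g. `stop_share`, `metric`).
#' @return An object of class `norms_phase_diagram`: a data frame with one
#'   row per cell: the axis values, counts `n_norm1`, `n_norm2`,
#'   `n_coexistence`, and the `majority` label.
#' @export
phase_sweep <- function(params, punish = punishment_config("none"),
                        axis1, axis2 = NULL, replicates = 5, seed = 1,
                        norm_threshold = 0.8, coexist_threshold = 0.8,
                        ...) {
  stopifnot(length(axis1$values) >= 1, replicates >= 1)
  v2 <- if (is.null(axis2)) NA else axis2$values
  cells <- expand.grid(i = seq_along(axis1$values), j = seq_along(v2))
  out <- lapply(seq_len(nrow(cells)), function(ci) {
    i <- cells$i[ci]; j <- cells$j[ci]
    upd <- set_swept_param(params, punish, axis1$param, axis1$values[i])
    if (!is.null(axis2))
      upd <- set_swept_param(upd$params, upd$punish, axis2$param,
                             axis2$values[j])
    labels <- vapply(seq_len(replicates), function(rep) {
      run <- run_simulation(upd$params, upd$punish,
                            seed = derive_seed(seed, i, j, rep), ...)
      classify_outcome(run$state, norm_threshold, coexist_threshold)
    }, character(1))
    counts <- table(factor(labels, c("norm1", "norm2", "coexistence")))
    cell <- data.frame(axis1 = axis1$values[i])
    names(cell) <- axis1$param
    if (!is.null(axis2)) {
      cell[[axis2$param]] <- axis2$values[j]
    }
    cell$n_norm1 <- as.integer(counts["norm1"])
    cell$n_norm2 <- as.integer(counts["norm2"])
    cell$n_coexistence <- as.integer(counts["coexistence"])
    cell$majority <- names(counts)[which.max(counts)]
    cell
  })
  structure(do.call(rbind, out),
            class = c("norms_phase_diagram", "data.frame"))
}
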
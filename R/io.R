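# Configuration files, grid snapshots, and CSV writers.

CONFIG_KEYS <- c("A", "B", "S", "p1", "p2", "R", "r", "n_rows", "n_cols",
                 "T", "seed", "metric", "mode", "C", "k", "C0", "L",
                 "mutual", "schedule")

#' Load a run configuration from a YAML file
#'
#' Reads a flat key-value document with any of the keys `A`, `B`, `S`,
#' `p1`, `p2`, `R`, `r`, `n_rows`, `n_cols`, `T`, `seed`, `metric`,
#' `mode`, `C`, `k`, `C0`, `L`, `mutual` and `schedule` (a list of
#' entries with `t0`, `param`, `value`). Missing keys take the baseline
#' defaults: A = 1, B = 0.5, R = 10, flip rate r = 0.01, punishment
#' disabled. Unknown keys and invariant violations are rejected.
#'
#' @param path Path to a YAML file. An empty file yields the baseline
#'   configuration.
#' @return A list with elements `params` ([sim_params()]), `punish`
#'   ([punishment_config()]), `sched` (schedule data frame or `NULL`) and
#'   `metric`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a key-value document")
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  config_from_list(cfg)
}

config_from_list <- function(cfg) {
  pk <- c("A", "B", "S", "p1", "p2", "R", "r", "n_rows", "n_cols", "T",
          "seed")
  params <- do.call(sim_params, cfg[intersect(names(cfg), pk)])
  punish <- punishment_config(
    mode = if (is.null(cfg$mode)) "none" else cfg$mode,
    C = if (is.null(cfg$C)) 0 else cfg$C,
    k = if (is.null(cfg$k)) 3 else cfg$k,
    C0 = if (is.null(cfg$C0)) 1 else cfg$C0,
    L = cfg$L,
    mutual = if (is.null(cfg$mutual)) TRUE else cfg$mutual)
  sched <- NULL
  if (!is.null(cfg$schedule)) {
    sched <- schedule(
      t0 = vapply(cfg$schedule, function(e) as.integer(e$t0), integer(1)),
      param = vapply(cfg$schedule, function(e) as.character(e$param),
                     character(1)),
      value = lapply(cfg$schedule, function(e) e$value))
  }
  metric <- if (is.null(cfg$metric)) "chebyshev" else
    match.arg(cfg$metric, c("chebyshev", "euclidean"))
  list(params = params, punish = punish, sched = sched, metric = metric)
}

# site code combining preference and behavior: 0 = prefers 1 & shows 1,
# 1 = prefers 1 & shows 2, 2 = prefers 2 & shows 1, 3 = prefers 2 & shows 2
state_codes <- function(state) {
  2L * (state$preference - 1L) + (state$behavior - 1L)
}

#' Write / read a grid snapshot
#'
#' The snapshot is a plain CSV matrix of integer site codes
#' `2*(preference - 1) + (behavior - 1)` in `{0, 1, 2, 3}` (the four
#' visual states: committed/deviant member of each population), one line
#' per lattice row. A JSON sidecar `<path>.meta.json` stores `t` and both
#' payoff matrices so that `read_snapshot(write_snapshot(state))`
#' round-trips exactly.
#'
#' @param state A `norms_grid`.
#' @param path Output CSV path.
#' @return `write_snapshot` returns `path` invisibly; `read_snapshot`
#'   returns a `norms_grid`.
#' @export
write_snapshot <- function(state, path) {
  codes <- state_codes(state)
  utils::write.table(codes, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(t = state$t,
               n_rows = nrow(codes), n_cols = ncol(codes),
               last_payoff = as.numeric(state$last_payoff),
               cumulative_payoff = as.numeric(state$cumulative_payoff))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  codes <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(codes) <- NULL
  storage.mode(codes) <- "integer"
  bad <- which(!(codes %in% 0:3))
  if (length(bad)) {
    stop(sprintf("invalid site code %d at line %d: codes must be 0..3",
                 codes[bad[1]], (bad[1] - 1) %% nrow(codes) + 1))
  }
  meta_path <- paste0(path, ".meta.json")
  state <- structure(list(
    preference = codes %/% 2L + 1L,
    behavior = codes %% 2L + 1L,
    last_payoff = matrix(0, nrow(codes), ncol(codes)),
    cumulative_payoff = matrix(0, nrow(codes), ncol(codes)),
    t = 0L), class = "norms_grid")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    state$t <- as.integer(meta$t)
    state$last_payoff <- matrix(meta$last_payoff, nrow(codes), ncol(codes))
    state$cumulative_payoff <- matrix(meta$cumulative_payoff,
                                      nrow(codes), ncol(codes))
  }
  state
}

resolved_config <- function(run) {
  c(unclass(run$params),
    list(mode = run$punish$mode, C = run$punish$C, k = run$punish$k,
         C0 = run$punish$C0, L = run$punish$L, mutual = run$punish$mutual,
         metric = run$metric, seed_used = run$seed))
}

#' Write run outputs to a directory
#'
#' Writes `timeseries.csv` (one row per step), the final snapshot
#' `snapshot_t<NNNN>.csv` (+ sidecar), `events.csv` when events were
#' recorded, and `params.json` with the fully resolved parameter set and
#' seed.
#'
#' @param run A `norms_run`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts <- run$timeseries
  ts$frac_sincere_punishers <-
    ts$n_sanctions_sincere / (run$params$n_rows * run$params$n_cols)
  ts$frac_hypocritical_punishers <-
    ts$n_sanctions_hypocritical / (run$params$n_rows * run$params$n_cols)
  utils::write.csv(ts, file.path(dir, "timeseries.csv"),
                   row.names = FALSE)
  write_snapshot(run$state,
                 file.path(dir, sprintf("snapshot_t%04d.csv",
                                        run$state$t)))
  if (!is.null(run$events) && nrow(run$events)) {
    ev <- run$events
    nr <- run$params$n_rows
    ev_out <- data.frame(
      t = ev$t,
      punisher_row = (ev$punisher - 1L) %% nr + 1L,
      punisher_col = (ev$punisher - 1L) %/% nr + 1L,
      punishee_row = (ev$punishee - 1L) %% nr + 1L,
      punishee_col = (ev$punishee - 1L) %/% nr + 1L,
      mode = ev$mode, label = ev$label, cost = ev$cost, fine = ev$fine)
    utils::write.csv(ev_out, file.path(dir, "events.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(resolved_config(run), file.path(dir, "params.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write a phase diagram as CSV
#'
#' @param pd A `norms_phase_diagram` from [phase_sweep()] or a data frame
#'   from [analytic_phase_diagram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phase_diagram <- function(pd, path) {
  utils::write.csv(as.data.frame(pd), path, row.names = FALSE)
  invisible(path)
}

#' Shipped scenario configurations
#'
#' Paths of the YAML scenario files installed with the package (the
#' regimes discussed in the methods vignette: path dependence, unpopular
#' norms, local cultures, coexistence, punishment contrast, punisher
#' typology, adaptive emergence, norm persistence).
#'
#' @param name Optional scenario name (file base name without extension).
#' @return A character vector of file paths, named by scenario.
#' @export
scenario_configs <- function(name = NULL) {
  dir <- system.file("extdata", package = "normsgame")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  names(files) <- sub("\\.yaml$", "", basename(files))
  if (!is.null(name)) {
    if (!name %in% names(files)) stop("unknown scenario: ", name)
    files <- files[name]
  }
  files
}
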
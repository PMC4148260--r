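# Outcome classification and order parameters.

#' Classify the final outcome of a run
#'
#' Labels a grid state as `norm1` or `norm2` when the corresponding
#' behavior is shown by at least `norm_threshold` of all agents, as
#' `coexistence` when at least `coexist_threshold` of agents show their
#' own preferred behavior, and otherwise by the largest of the three
#' shares (ties resolve to coexistence). The underlying phases are visual:
#' a nearly uniform grid of one behavior versus a salt-and-pepper mix in
#' which everybody does what they prefer; the thresholds make that
#' distinction operational.
#'
#' @param state A `norms_grid`.
#' @param norm_threshold,coexist_threshold Classification thresholds in
#'   `(0.5, 1]`.
#' @return One of `"norm1"`, `"norm2"`, `"coexistence"`.
#' @export
classify_outcome <- function(state, norm_threshold = 0.8,
                             coexist_threshold = 0.8) {
  stopifnot(norm_threshold > 0.5, norm_threshold <= 1,
            coexist_threshold > 0.5, coexist_threshold <= 1)
  sh <- grid_shares(state)
  if (sh["share_b1"] >= norm_threshold) return("norm1")
  if (sh["share_b2"] >= norm_threshold) return("norm2")
  if (sh["share_preferred"] >= coexist_threshold) return("coexistence")
  lab <- c("norm1", "norm2", "coexistence")
  best <- which(sh == max(sh))
  if (length(best) > 1) "coexistence" else lab[best]
}

#' Mean local behavioral conformity
#'
#' Average over all agents of the fraction of range-`R` neighbors showing
#' the same behavior as the agent. A uniform grid scores 1; an i.i.d.
#' random grid scores about `s1^2 + s2^2` where `s1`, `s2` are the global
#' behavior shares. High local conformity combined with intermediate
#' global shares indicates local cultures: patches of local consensus with
#' global diversity.
#'
#' @param state A `norms_grid`.
#' @param R Interaction range.
#' @param metric Distance metric, see [neighborhood_offsets()].
#' @return Fraction in `[0, 1]`.
#' @export
local_conformity <- function(state, R, metric = "chebyshev") {
  off <- neighborhood_offsets(R, metric)
  b <- state$behavior
  nr <- nrow(b); nc <- ncol(b)
  agree <- matrix(0, nr, nc)
  for (o in seq_len(nrow(off))) {
    rows <- (seq_len(nr) - 1 + off[o, 1]) %% nr + 1
    cols <- (seq_len(nc) - 1 + off[o, 2]) %% nc + 1
    agree <- agree + (b == b[rows, cols, drop = FALSE])
  }
  mean(agree / nrow(off))
}

#' Punisher-type proportions over time
#'
#' Aggregates a sanction event log into windows of `window` steps and
#' reports, per window: sanction events per agent per step split by label
#' (the paper-style "proportion of sincere/hypocritical punishers"), the
#' fraction of events of each label, and the fraction of agents that
#' punished at least once in the window.
#'
#' @param events Event data frame from [run_simulation()] (needs columns
#'   `t`, `punisher`, `hypocritical`).
#' @param n_agents Number of agents on the lattice.
#' @param window Window length in steps.
#' @param t_max Last step to include (defaults to the last event).
#' @return Data frame with one row per window.
#' @export
punisher_proportions <- function(events, n_agents, window = 10L,
                                 t_max = NULL) {
  if (is.null(t_max)) t_max <- if (nrow(events)) max(events$t) else 0L
  breaks <- seq(0L, max(window, as.integer(ceiling(t_max / window)) * window),
                by = window)
  out <- lapply(seq_len(length(breaks) - 1L), function(i) {
    sel <- events$t > breaks[i] & events$t <= breaks[i + 1L]
    e <- events[sel, , drop = FALSE]
    steps <- breaks[i + 1L] - breaks[i]
    data.frame(
      t_start = breaks[i] + 1L, t_end = breaks[i + 1L],
      rate_sincere = sum(e$hypocritical == 0) / (n_agents * steps),
      rate_hypocritical = sum(e$hypocritical == 1) / (n_agents * steps),
      frac_events_sincere =
        if (nrow(e)) mean(e$hypocritical == 0) else 0,
      frac_events_hypocritical =
        if (nrow(e)) mean(e$hypocritical == 1) else 0,
      frac_agents_punishing =
        length(unique(e$punisher)) / n_agents)
  })
  do.call(rbind, out)
}
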
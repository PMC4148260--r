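# Random-sequential update dynamics: interaction, in-group proportional
# imitation, random strategy flipping. The pure-R engine in this file
# consumes the global RNG stream in exactly the same order as the compiled
# engine (focal site, partner offset, role model / adoption per agent,
# noise per agent), so both engines produce bit-identical trajectories
# from the same seed -- a property the test suite relies on.

# 0-based uniform integer on {0, ..., n-1}, one uniform consumed
draw_int_r <- function(n) {
  j <- as.integer(stats::runif(1) * n)
  if (j >= n) j <- n - 1L
  j
}

# neighbor of 1-based linear index under offset row o (column-major grid)
nbr_idx <- function(idx, o, off, n_rows, n_cols) {
  row <- (idx - 1L) %% n_rows
  col <- (idx - 1L) %/% n_rows
  nr <- (row + off[o, 1L]) %% n_rows
  nc <- (col + off[o, 2L]) %% n_cols
  nr + nc * n_rows + 1L
}

lin_to_site <- function(idx, n_rows) {
  c(row = (idx - 1L) %% n_rows + 1L, col = (idx - 1L) %/% n_rows + 1L)
}

site_to_lin <- function(site, n_rows) {
  as.integer(site[1]) - 1L + (as.integer(site[2]) - 1L) * n_rows + 1L
}

#' Choose a uniform interaction partner within range R
#'
#' @param state A `norms_grid`.
#' @param focal Site `c(row, col)` of the focal agent.
#' @param R Interaction range.
#' @param metric Distance metric, see [neighborhood_offsets()].
#' @return Site `c(row, col)` of the chosen partner.
#' @export
choose_partner <- function(state, focal, R, metric = "chebyshev") {
  off <- neighborhood_offsets(R, metric)
  n_rows <- nrow(state$behavior)
  idx <- nbr_idx(site_to_lin(focal, n_rows), draw_int_r(nrow(off)) + 1L,
                 off, n_rows, ncol(state$behavior))
  lin_to_site(idx, n_rows)
}

#' Choose a role model: a uniform same-preference neighbor
#'
#' Imitation is restricted to the in-group: only neighbors sharing the
#' focal agent's preference are eligible. Returns `NULL` when no neighbor
#' within range shares the preference.
#'
#' @inheritParams choose_partner
#' @return Site `c(row, col)` or `NULL`.
#' @export
choose_role_model <- function(state, focal, R, metric = "chebyshev") {
  off <- neighborhood_offsets(R, metric)
  n_rows <- nrow(state$behavior)
  n_cols <- ncol(state$behavior)
  i0 <- site_to_lin(focal, n_rows)
  pref <- state$preference
  nb <- vapply(seq_len(nrow(off)), function(o)
    nbr_idx(i0, o, off, n_rows, n_cols), integer(1))
  eligible <- nb[pref[nb] == pref[i0]]
  if (length(eligible) == 0L) return(NULL)
  lin_to_site(eligible[draw_int_r(length(eligible)) + 1L], n_rows)
}

#' Proportional imitation of a more successful in-group role model
#'
#' The agent adopts the role model's behavior with probability
#' `min(1, (P_model - P_agent) / (A + B))` when the model's last
#' interaction payoff is strictly higher; otherwise it keeps its behavior.
#' Clipping at 1 only matters under punishment, where payoff differences
#' can exceed `A + B`.
#'
#' @param state A `norms_grid`.
#' @param agent Site `c(row, col)` of the imitating agent.
#' @param role_model Site `c(row, col)` or `NULL` (no eligible model).
#' @param params A [sim_params()] object.
#' @return List with the updated `state` and logical `switched`.
#' @export
imitation_update <- function(state, agent, role_model, params) {
  if (is.null(role_model)) return(list(state = state, switched = FALSE))
  if (state$preference[agent[1], agent[2]] !=
      state$preference[role_model[1], role_model[2]])
    stop("role model must share the agent's preference")
  d <- state$last_payoff[role_model[1], role_model[2]] -
       state$last_payoff[agent[1], agent[2]]
  if (d <= 0) return(list(state = state, switched = FALSE))
  prob <- min(1, d / (params$A + params$B))
  switched <- stats::runif(1) < prob
  if (switched) {
    new_b <- state$behavior[role_model[1], role_model[2]]
    switched <- state$behavior[agent[1], agent[2]] != new_b
    state$behavior[agent[1], agent[2]] <- new_b
  }
  list(state = state, switched = switched)
}

#' Random strategy flipping
#'
#' With probability `r` the agent switches to the opposite behavior; its
#' preference is untouched.
#'
#' @param state A `norms_grid`.
#' @param agent Site `c(row, col)`.
#' @param r Flip probability in `[0, 1]`.
#' @return List with the updated `state` and logical `flipped`.
#' @export
noise_update <- function(state, agent, r) {
  flipped <- stats::runif(1) < r
  if (flipped)
    state$behavior[agent[1], agent[2]] <-
      3L - state$behavior[agent[1], agent[2]]
  list(state = state, flipped = flipped)
}

# One full step (N/2 rounds) in pure R, mirroring the compiled engine's
# RNG consumption exactly. Internal; advance_step() is the public wrapper.
step_r <- function(pref, beh, lp, cum, n_rows, n_cols, t,
                   A, B, r, off, mode_code, C, k_fine, C0,
                   mutual, record_events) {
  n <- n_rows * n_cols
  n_off <- nrow(off)
  sin_count <- 0L; hyp_count <- 0L
  total_gross <- 0
  ev <- list(t = integer(0), punisher = integer(0), punishee = integer(0),
             hypocritical = integer(0), cost = numeric(0), fine = numeric(0))

  nonconf <- function(ego) {
    d <- 0L
    for (o in seq_len(n_off))
      if (beh[nbr_idx(ego, o, off, n_rows, n_cols)] != beh[ego]) d <- d + 1L
    d / n_off
  }

  for (round in seq_len(n %/% 2L)) {
    focal <- draw_int_r(n) + 1L
    partner <- nbr_idx(focal, draw_int_r(n_off) + 1L, off, n_rows, n_cols)
    Pb <- A * (beh[focal] == beh[partner]) + B * (beh[focal] == pref[focal])
    Pc <- A * (beh[partner] == beh[focal]) + B * (beh[partner] == pref[partner])
    total_gross <- total_gross + Pb + Pc
    net <- c(Pb, Pc)  # focal, partner

    if (mode_code > 0L) {
      pairs <- if (mutual) list(c(1L, 2L), c(2L, 1L)) else list(c(1L, 2L))
      agents <- c(focal, partner)
      for (pr in pairs) {
        ego <- agents[pr[1]]; alter <- agents[pr[2]]
        trigger <- if (mode_code == 2L) beh[alter] != pref[ego]
                   else beh[alter] != beh[ego]
        if (!trigger) next
        cost <- if (mode_code == 3L) {
          u <- 1 - nonconf(ego)
          C0 * u^4 * (2 - u^2)^2
        } else C
        if (cum[ego] - cost < 0) next
        fine <- k_fine * cost
        cum[ego] <- cum[ego] - cost
        cum[alter] <- cum[alter] - fine
        net[pr[1]] <- net[pr[1]] - cost
        net[pr[2]] <- net[pr[2]] - fine
        hyp <- if (mode_code == 2L) beh[alter] == beh[ego]
               else beh[alter] == pref[ego]
        if (hyp) hyp_count <- hyp_count + 1L else sin_count <- sin_count + 1L
        if (record_events) {
          ev$t <- c(ev$t, t + 1L); ev$punisher <- c(ev$punisher, ego)
          ev$punishee <- c(ev$punishee, alter)
          ev$hypocritical <- c(ev$hypocritical, as.integer(hyp))
          ev$cost <- c(ev$cost, cost); ev$fine <- c(ev$fine, fine)
        }
      }
    }

    lp[focal] <- net[1]; lp[partner] <- net[2]
    cum[focal] <- cum[focal] + Pb
    cum[partner] <- cum[partner] + Pc

    for (agent in c(focal, partner)) {
      m <- 0L
      for (o in seq_len(n_off))
        if (pref[nbr_idx(agent, o, off, n_rows, n_cols)] == pref[agent])
          m <- m + 1L
      if (m > 0L) {
        pick <- draw_int_r(m)
        model <- NA_integer_
        for (o in seq_len(n_off)) {
          s <- nbr_idx(agent, o, off, n_rows, n_cols)
          if (pref[s] == pref[agent]) {
            if (pick == 0L) { model <- s; break }
            pick <- pick - 1L
          }
        }
        d <- lp[model] - lp[agent]
        if (d > 0) {
          prob <- min(1, d / (A + B))
          if (stats::runif(1) < prob) beh[agent] <- beh[model]
        }
      }
    }
    for (agent in c(focal, partner))
      if (stats::runif(1) < r) beh[agent] <- 3L - beh[agent]
  }

  list(pref = pref, beh = beh, lp = lp, cum = cum, t = t + 1L,
       sin = sin_count, hyp = hyp_count, total_gross = total_gross,
       events = ev)
}

#' Advance the simulation by one time step
#'
#' Performs `N / 2` rounds of the random-sequential update. Each round
#' draws a focal agent uniformly (with replacement) and a partner within
#' range `R`, computes interaction payoffs, applies any configured
#' sanctions, then lets focal and partner independently imitate an
#' in-group role model and finally flip behavior with probability `r`.
#' Afterwards `t` is incremented and per-step aggregates are computed.
#'
#' This is the reference (pure R) implementation; [run_simulation()] uses
#' the compiled engine by default, which follows the identical update and
#' RNG schedule.
#'
#' @param state A `norms_grid`.
#' @param params A [sim_params()] object.
#' @param punish A [punishment_config()] object.
#' @param metric Distance metric, see [neighborhood_offsets()].
#' @param record_events If `TRUE`, individual sanction events are
#'   returned.
#' @return List with updated `state`, a one-row data frame `metrics`
#'   (columns `t`, `share_b1`, `share_preferred`, `mean_payoff`,
#'   `n_sanctions_sincere`, `n_sanctions_hypocritical`), a data frame
#'   `events`, and `total_gross_payoff` (sum of the interaction payoffs
#'   assigned this step, before punishment deductions).
#' @examples
#' set.seed(1)
#' p <- sim_params(n_rows = 10, n_cols = 10, R = 1)
#' st <- init_grid(p)
#' out <- advance_step(st, p)
#' out$metrics
#' @export
advance_step <- function(state, params, punish = punishment_config("none"),
                         metric = "chebyshev", record_events = FALSE) {
  off <- neighborhood_offsets(params$R, metric)
  res <- step_r(as.integer(state$preference), as.integer(state$behavior),
                as.numeric(state$last_payoff),
                as.numeric(state$cumulative_payoff),
                nrow(state$behavior), ncol(state$behavior), state$t,
                params$A, params$B, params$r, off,
                punish_mode_code(punish), punish$C, punish$k, punish$C0,
                punish$mutual, record_events)
  dims <- dim(state$behavior)
  state$behavior <- matrix(res$beh, dims[1], dims[2])
  state$last_payoff <- matrix(res$lp, dims[1], dims[2])
  state$cumulative_payoff <- matrix(res$cum, dims[1], dims[2])
  state$t <- res$t
  metrics <- data.frame(
    t = res$t,
    share_b1 = mean(res$beh == 1L),
    share_preferred = mean(res$beh == res$pref),
    mean_payoff = mean(res$lp),
    n_sanctions_sincere = res$sin,
    n_sanctions_hypocritical = res$hyp)
  list(state = state, metrics = metrics,
       events = as.data.frame(res$events),
       total_gross_payoff = res$total_gross)
}
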
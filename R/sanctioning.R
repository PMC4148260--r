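# Costly peer punishment: behavior-based, preference-based, and adaptive
# group pressure, with sincere vs hypocritical classification.

#' Adaptive group-pressure punishment cost
#'
#' Punishment cost as a function of the relative frequency `N` of
#' non-conforming behavior within the punisher's interaction range:
#' `C(N) = C0 * (1 - N)^4 * (2 - (1 - N)^2)^2`. The cost equals the
#' maximum level `C0` when everybody conforms (`N = 0`), drops steeply
#' once non-conformity becomes common, and vanishes when nobody conforms
#' (`N = 1`): local majorities sanction hard, local minorities do not dare
#' to sanction at all.
#'
#' @param nonconform_frac Relative frequency of non-conforming behavior in
#'   `[0, 1]` (vectorized).
#' @param C0 Maximum punishment cost.
#' @return Punishment cost(s) in payoff units.
#' @examples
#' adaptive_cost(0, 1)    # 1
#' adaptive_cost(1, 1)    # 0
#' adaptive_cost(0.5, 1)  # 49/256
#' @export
adaptive_cost <- function(nonconform_frac, C0 = 1) {
  if (any(nonconform_frac < 0 | nonconform_frac > 1))
    stop("'nonconform_frac' must lie in [0, 1]")
  u <- 1 - nonconform_frac
  C0 * u^4 * (2 - u^2)^2
}

#' Local frequency of non-conforming behavior
#'
#' Fraction of the agent's range-`R` neighbors (self excluded, current
#' interaction partner included) whose displayed behavior differs from the
#' agent's own displayed behavior.
#'
#' @param state A `norms_grid`.
#' @param ego Site `c(row, col)`.
#' @param R Interaction range.
#' @param metric Distance metric, see [neighborhood_offsets()].
#' @return Fraction in `[0, 1]`.
#' @export
nonconforming_fraction <- function(state, ego, R, metric = "chebyshev") {
  nb <- neighborhood(ego, R, dim(state$behavior), metric)
  b <- state$behavior[cbind(nb[, "row"], nb[, "col"])]
  mean(b != state$behavior[ego[1], ego[2]])
}

#' Decide whether ego sanctions alter
#'
#' Behavior-based (and adaptive) punishment triggers when alter's behavior
#' differs from ego's displayed behavior; preference-based punishment
#' triggers when alter's behavior differs from ego's private preference.
#' In every mode the sanction is vetoed when paying the cost would make
#' ego's cumulative payoff negative (checked before this round's
#' interaction payoff is credited).
#'
#' @param state A `norms_grid`.
#' @param ego,alter Sites `c(row, col)`.
#' @param punish A [punishment_config()] object.
#' @param metric Distance metric (adaptive mode evaluates the local
#'   non-conformity within range given by `R`).
#' @param R Interaction range (adaptive mode only).
#' @return List with logical `trigger`, and the `cost` and `fine` that
#'   would apply.
#' @export
punish_decision <- function(state, ego, alter, punish, R = NULL,
                            metric = "chebyshev") {
  if (punish$mode == "none")
    return(list(trigger = FALSE, cost = 0, fine = 0))
  b_ego <- state$behavior[ego[1], ego[2]]
  b_alt <- state$behavior[alter[1], alter[2]]
  trigger <- switch(punish$mode,
    behavior = ,
    adaptive = b_alt != b_ego,
    preference = b_alt != state$preference[ego[1], ego[2]])
  cost <- if (punish$mode == "adaptive") {
    if (is.null(R)) stop("adaptive mode needs the interaction range 'R'")
    adaptive_cost(nonconforming_fraction(state, ego, R, metric), punish$C0)
  } else punish$C
  if (trigger && state$cumulative_payoff[ego[1], ego[2]] - cost < 0)
    trigger <- FALSE
  list(trigger = trigger, cost = cost, fine = punish$k * cost)
}

#' Classify a sanction as sincere or hypocritical
#'
#' A punisher is hypocritical when she sanctions what actually conforms to
#' her own standard: in behavior-based (and adaptive) mode, when the
#' punished behavior equals her private preference (she punishes others
#' for doing what she herself would prefer to do); in preference-based
#' mode, when the punished behavior equals her own displayed behavior (she
#' punishes others for the very behavior she shows herself).
#'
#' @param state A `norms_grid`.
#' @param ego,alter Punisher and punishee sites `c(row, col)`.
#' @param mode Punishment mode, one of `"behavior"`, `"preference"`,
#'   `"adaptive"`.
#' @return `"sincere"` or `"hypocritical"`.
#' @export
classify_punishment <- function(state, ego, alter,
                                mode = c("behavior", "preference",
                                         "adaptive")) {
  mode <- match.arg(mode)
  b_alt <- state$behavior[alter[1], alter[2]]
  hyp <- if (mode == "preference") {
    b_alt == state$behavior[ego[1], ego[2]]
  } else {
    b_alt == state$preference[ego[1], ego[2]]
  }
  if (hyp) "hypocritical" else "sincere"
}

#' Apply an established sanction to the round payoffs
#'
#' Deducts the cost from the punisher's round payoff and the fine from the
#' punishee's, and updates both cumulative payoffs. Fines may drive
#' payoffs negative; only the punisher is protected by the solvency guard
#' in [punish_decision()].
#'
#' @param state A `norms_grid`.
#' @param ego,alter Punisher and punishee sites `c(row, col)`.
#' @param cost,fine Payoff deductions.
#' @return The updated `norms_grid`.
#' @export
apply_punishment <- function(state, ego, alter, cost, fine) {
  state$last_payoff[ego[1], ego[2]] <-
    state$last_payoff[ego[1], ego[2]] - cost
  state$last_payoff[alter[1], alter[2]] <-
    state$last_payoff[alter[1], alter[2]] - fine
  state$cumulative_payoff[ego[1], ego[2]] <-
    state$cumulative_payoff[ego[1], ego[2]] - cost
  state$cumulative_payoff[alter[1], alter[2]] <-
    state$cumulative_payoff[alter[1], alter[2]] - fine
  state
}
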
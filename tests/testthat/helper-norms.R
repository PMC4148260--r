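# Small fixture builders shared across test files.

tiny_params <- function(...) {
  args <- list(...)
  defaults <- list(n_rows = 10L, n_cols = 10L, R = 1L, T = 10L)
  do.call(sim_params, utils::modifyList(defaults, args))
}

# grid with hand-set preference/behavior matrices (payoffs zero, t = 0)
manual_grid <- function(preference, behavior,
                        last_payoff = NULL, cumulative_payoff = NULL) {
  stopifnot(identical(dim(preference), dim(behavior)))
  if (is.null(last_payoff)) last_payoff <- array(0, dim(preference))
  if (is.null(cumulative_payoff)) cumulative_payoff <- array(0, dim(preference))
  structure(list(preference = preference, behavior = behavior,
                 last_payoff = last_payoff,
                 cumulative_payoff = cumulative_payoff, t = 0L),
            class = "norms_grid")
}

# uniform grid: everyone prefers `pref` and shows `beh`
uniform_grid <- function(n = 6, pref = 1L, beh = 1L) {
  manual_grid(matrix(as.integer(pref), n, n), matrix(as.integer(beh), n, n))
}
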
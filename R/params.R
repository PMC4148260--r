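#' Simulation parameters for the multi-population norms game
#'
#' Bundles and validates every scalar parameter of the lattice model.
#' `A` is the advantage of conforming with the behavior of the interaction
#' partner, `B` the benefit of showing the privately preferred behavior;
#' the interesting regimes are `A > B` (conformity pays more than
#' preference) and `B > A` (coexistence unless sanctions are applied).
#'
#' @param A Advantage of conforming (payoff units, `A > 0`).
#' @param B Benefit of showing the preferred behavior (payoff units,
#'   `B >= 0`).
#' @param S Share of agents belonging to population 1, the population
#'   preferring behavior 1 (fraction in `[0, 1]`).
#' @param p1,p2 Initial commitment of population 1 and 2: the fraction of
#'   each population that starts out displaying its preferred behavior.
#' @param R Interaction range: agents interact with all sites within
#'   Chebyshev distance `R` on the torus (positive integer,
#'   `2 * R + 1 <= min(n_rows, n_cols)` so the neighborhood cannot wrap
#'   onto itself).
#' @param r Per-update probability of a random strategy flip in `[0, 1]`.
#' @param n_rows,n_cols Lattice dimensions; the grid is fully occupied so
#'   the number of agents is `n_rows * n_cols`.
#' @param T Number of simulation steps; one step updates `N / 2` focal
#'   agents and their interaction partners (`N` agents in total).
#' @param seed Integer RNG seed used by [run_simulation()] unless
#'   overridden.
#'
#' @return An object of class `norms_params` (a named list).
#' @examples
#' p <- sim_params(S = 0.8, p1 = 0.25, p2 = 0.9, n_rows = 20, n_cols = 20)
#' p$A
#' @export
sim_params <- function(A = 1, B = 0.5, S = 0.5, p1 = 0.5, p2 = 0.5,
                       R = 10L, r = 0.01, n_rows = 50L, n_cols = 50L,
                       T = 200L, seed = 1L) {
  stopifnot(is.numeric(A), length(A) == 1, A > 0,
            is.numeric(B), length(B) == 1, B >= 0)
  for (nm in c("S", "p1", "p2", "r")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single value in [0, 1]", nm))
  }
  R <- as.integer(R); n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  T <- as.integer(T); seed <- as.integer(seed)
  if (is.na(R) || R < 1) stop("'R' must be a positive integer")
  if (n_rows * n_cols < 2) stop("the lattice must hold at least 2 agents")
  if (2L * R + 1L > min(n_rows, n_cols))
    stop("interaction range too large: 2*R + 1 must not exceed min(n_rows, n_cols)")
  if (T < 0) stop("'T' must be non-negative")
  structure(list(A = A, B = B, S = S, p1 = p1, p2 = p2, R = R, r = r,
                 n_rows = n_rows, n_cols = n_cols, T = T, seed = seed),
            class = "norms_params")
}

#' @export
print.norms_params <- function(x, ...) {
  cat("Multi-population norms game parameters\n")
  cat(sprintf("  payoffs: A = %g, B = %g (B/A = %g)\n", x$A, x$B, x$B / x$A))
  cat(sprintf("  populations: S = %g, commitments p1 = %g, p2 = %g\n",
              x$S, x$p1, x$p2))
  cat(sprintf("  lattice: %d x %d torus, range R = %d, flip rate r = %g\n",
              x$n_rows, x$n_cols, x$R, x$r))
  cat(sprintf("  horizon: T = %d steps, seed = %d\n", x$T, x$seed))
  invisible(x)
}

#' Peer-punishment configuration
#'
#' Configures the sanctioning stage of an interaction. In the constant
#' modes each sanction costs the punisher `C` and fines the punishee
#' `F = k * C`; the combined severity is the punishment level
#' `L = (k + 1) * C`. In adaptive mode the cost is recomputed per sanction
#' from the local frequency of non-conforming behavior via
#' [adaptive_cost()] with maximum level `C0`.
#'
#' @param mode One of `"none"`, `"behavior"` (sanction partners whose
#'   behavior differs from the punisher's displayed behavior),
#'   `"preference"` (sanction partners whose behavior differs from the
#'   punisher's private preference), `"adaptive"` (behavior-based trigger
#'   with group-pressure-dependent cost).
#' @param C Punishment cost per sanction (payoff units, constant modes).
#' @param k Fine multiplier, `k > 1`; the fine is `F = k * C`.
#' @param C0 Maximum punishment cost (adaptive mode).
#' @param L Optional punishment level; when supplied, `C` is derived as
#'   `L / (k + 1)` (constant modes).
#' @param mutual If `TRUE` (default) both interaction partners evaluate
#'   sanctioning each other within the same interaction, in
#'   focal-then-partner order; if `FALSE` only the focal agent may
#'   sanction.
#'
#' @return An object of class `norms_punishment` with fields `mode`, `C`,
#'   `k`, `C0`, `L` and `mutual`.
#' @examples
#' punishment_config("behavior", L = 1.5, k = 3)$C  # 0.375
#' @export
punishment_config <- function(mode = c("none", "behavior", "preference",
                                       "adaptive"),
                              C = 0, k = 3, C0 = 1, L = NULL,
                              mutual = TRUE) {
  mode <- match.arg(mode)
  if (mode != "none" && k <= 1)
    stop("'k' must exceed 1: the fine F = k*C is assumed larger than the cost C")
  if (!is.null(L)) {
    if (L < 0) stop("'L' must be non-negative")
    C <- L / (k + 1)
  }
  if (C < 0 || C0 < 0) stop("'C' and 'C0' must be non-negative")
  structure(list(mode = mode, C = C, k = k, C0 = C0, L = (k + 1) * C,
                 mutual = isTRUE(mutual)),
            class = "norms_punishment")
}

#' @export
print.norms_punishment <- function(x, ...) {
  if (x$mode == "none") {
    cat("Punishment disabled\n")
  } else if (x$mode == "adaptive") {
    cat(sprintf("Adaptive group pressure: C0 = %g, k = %g, %s\n",
                x$C0, x$k, if (x$mutual) "mutual" else "focal-only"))
  } else {
    cat(sprintf("%s-based punishment: C = %g, k = %g (F = %g, L = %g), %s\n",
                x$mode, x$C, x$k, x$k * x$C, x$L,
                if (x$mutual) "mutual" else "focal-only"))
  }
  invisible(x)
}

# integer code for the C++ engine
punish_mode_code <- function(punish) {
  match(punish$mode, c("none", "behavior", "preference", "adaptive")) - 1L
}
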
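# Representative-agent (mean-field) oracle for the norms game without
# spatial structure, used to validate the lattice simulator at large
# interaction ranges.

#' Mean-field switching condition
#'
#' A focal agent showing its preferred behavior, surrounded by a share `s`
#' of conforming agents, earns `B + s*A`; switching to the non-preferred
#' behavior would earn `(1 - s)*A`. A payoff-maximizing agent therefore
#' abandons its preference iff `B/A < 1 - 2*s`.
#'
#' @param A Advantage of conforming, `A > 0`.
#' @param B Benefit of the preferred behavior.
#' @param s Share of agents currently conforming with the focal agent's
#'   (preferred) behavior, in `[0, 1]`.
#' @return Logical: `TRUE` if switching away from the preference pays.
#' @examples
#' switch_condition(A = 1, B = 0.2, s = 0.2)  # TRUE:  0.2 < 0.6
#' switch_condition(A = 1, B = 0.5, s = 0.3)  # FALSE: 0.5 < 0.4 fails
#' @export
switch_condition <- function(A, B, s) {
  stopifnot(A > 0, s >= 0, s <= 1)
  B / A < 1 - 2 * s
}

#' Mean-field switching condition under behavior-based punishment
#'
#' Punishment effectively raises the advantage of conforming: with cost
#' `C` and fine `F` the condition `B + s*A < (1 - s)*A` becomes
#' `B < (1 - 2*s) * (A + C + F)`. With `C = F = 0` this reduces to
#' [switch_condition()].
#'
#' @inheritParams switch_condition
#' @param C Punishment cost, `C >= 0`.
#' @param F Punishment fine, `F >= 0`.
#' @return Logical: `TRUE` if switching away from the preference pays.
#' @examples
#' switch_condition_punished(A = 1, B = 1.2, s = 0.2, C = 0.5, F = 1.5)
#' @export
switch_condition_punished <- function(A, B, s, C = 0, F = 0) {
  stopifnot(A > 0, s >= 0, s <= 1, C >= 0, F >= 0)
  B < (1 - 2 * s) * (A + C + F)
}

#' Mean-field phase prediction
#'
#' Predicts the long-run outcome for population strength `S`: behavior 2
#' becomes the norm when members of population 1 would switch at
#' conforming share `s = S`; behavior 1 becomes the norm in the mirror
#' case (`s = 1 - S`, by the 1-2 relabeling symmetry of the game);
#' otherwise the two behaviors coexist, with most agents showing their own
#' preference. Points exactly on a separating line are labeled
#' coexistence.
#'
#' @inheritParams switch_condition_punished
#' @param S Share of agents preferring behavior 1.
#' @return One of `"norm1"`, `"norm2"`, `"coexistence"`.
#' @examples
#' predicted_phase(A = 1, B = 0.5, S = 0.1)  # "norm2"
#' predicted_phase(A = 1, B = 0.5, S = 0.5)  # "coexistence"
#' predicted_phase(A = 1, B = 0.5, S = 0.9)  # "norm1"
#' @export
predicted_phase <- function(A, B, S, C = 0, F = 0) {
  to2 <- switch_condition_punished(A, B, s = S, C = C, F = F)
  to1 <- switch_condition_punished(A, B, s = 1 - S, C = C, F = F)
  if (to2 && to1)
    stop("degenerate parameters: both populations predicted to switch")
  if (to2) "norm2" else if (to1) "norm1" else "coexistence"
}

#' Analytic phase diagram over (B/A, S)
#'
#' Evaluates [predicted_phase()] on a grid of relative benefits and
#' population strengths.
#'
#' @param BA Numeric vector of `B/A` ratios.
#' @param S Numeric vector of population-1 shares.
#' @inheritParams switch_condition_punished
#' @return Data frame with columns `BA`, `S`, `label`.
#' @export
analytic_phase_diagram <- function(BA = seq(0, 1, by = 0.02),
                                   S = seq(0, 1, by = 0.02),
                                   A = 1, C = 0, F = 0) {
  g <- expand.grid(BA = BA, S = S)
  g$label <- vapply(seq_len(nrow(g)), function(i)
    predicted_phase(A, g$BA[i] * A, g$S[i], C, F), character(1))
  g
}
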
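#' Neighborhood offsets for a given interaction range
#'
#' Enumerates the relative coordinates of all sites within range `R` of a
#' focal site, excluding the focal site itself, in deterministic row-major
#' order. The default Chebyshev metric yields the Moore neighborhood of
#' `(2R + 1)^2 - 1` sites, which gives every agent on the torus the same
#' number of neighbors; the Euclidean option keeps offsets with
#' `dr^2 + dc^2 <= R^2`.
#'
#' @param R Interaction range (positive integer).
#' @param metric `"chebyshev"` (default) or `"euclidean"`.
#' @return Integer matrix with columns `dr`, `dc`.
#' @examples
#' nrow(neighborhood_offsets(1))   # 8
#' nrow(neighborhood_offsets(2))   # 24
#' @export
neighborhood_offsets <- function(R, metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  R <- as.integer(R)
  stopifnot(R >= 1)
  g <- expand.grid(dc = -R:R, dr = -R:R)   # row-major: dr outer, dc inner
  g <- g[order(g$dr, g$dc), c("dr", "dc")]
  g <- g[!(g$dr == 0 & g$dc == 0), , drop = FALSE]
  if (metric == "euclidean")
    g <- g[g$dr^2 + g$dc^2 <= R^2, , drop = FALSE]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("dr", "dc"))
  storage.mode(m) <- "integer"
  m
}

#' Toroidal neighborhood of a lattice site
#'
#' All sites within range `R` of `site` under toroidal wrap-around,
#' excluding `site` itself.
#'
#' @param site Integer vector `c(row, col)`, 1-based.
#' @param R Interaction range.
#' @param dims Integer vector `c(n_rows, n_cols)`.
#' @param metric Distance metric, see [neighborhood_offsets()].
#' @return Integer matrix with columns `row`, `col` (1-based coordinates).
#' @examples
#' nrow(neighborhood(c(1, 1), R = 1, dims = c(5, 5)))  # 8, wraps at edges
#' @export
neighborhood <- function(site, R, dims, metric = c("chebyshev", "euclidean")) {
  if (2L * R + 1L > min(dims))
    stop("neighborhood would wrap onto itself: 2*R + 1 exceeds min(dims)")
  off <- neighborhood_offsets(R, metric)
  row <- (site[1] - 1L + off[, "dr"]) %% dims[1] + 1L
  col <- (site[2] - 1L + off[, "dc"]) %% dims[2] + 1L
  cbind(row = row, col = col)
}

#' Pairwise interaction payoff
#'
#' Payoff of a focal agent showing behavior `b` against a partner showing
#' `c`, given the focal agent's preference `p`: an advantage `A` for
#' conforming (`b == c`) plus a benefit `B` for displaying the preferred
#' behavior (`b == p`). The four cells are `A + B`, `B`, `A` and `0`.
#'
#' @param b,c,p Behavior of the focal agent, behavior of the partner, and
#'   preference of the focal agent; each 1 or 2 (vectorized).
#' @param params A [sim_params()] object (only `A` and `B` are used).
#' @return Numeric payoff(s).
#' @examples
#' p <- sim_params(A = 1, B = 0.5)
#' payoff_pair(1, 1, 1, p)  # A + B = 1.5
#' payoff_pair(1, 2, 2, p)  # 0
#' @export
payoff_pair <- function(b, c, p, params) {
  stopifnot(all(b %in% 1:2), all(c %in% 1:2), all(p %in% 1:2))
  params$A * (b == c) + params$B * (b == p)
}

#' Initialize the agent lattice
#'
#' Distributes the two preferences uniformly at random over the grid with
#' exact counts (`round(S * N)` sites prefer behavior 1), then assigns
#' initial behaviors so that exactly `round(p1 * |pop1|)` members of
#' population 1 start with behavior 1, and analogously for population 2.
#' Exact assignment (rather than independent Bernoulli draws) removes
#' initialization variance from replicate experiments. Payoffs start at 0
#' and `t = 0`. Uses the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `norms_grid`: a list with integer matrices
#'   `preference` and `behavior` (values 1/2), numeric matrices
#'   `last_payoff` and `cumulative_payoff`, and scalar `t`.
#' @examples
#' set.seed(1)
#' g <- init_grid(sim_params(S = 0.8, n_rows = 10, n_cols = 10))
#' sum(g$preference == 1)  # exactly 80
#' @export
init_grid <- function(params) {
  n <- params$n_rows * params$n_cols
  n1 <- round(params$S * n)
  if (n1 == 0 || n1 == n)
    warning("one population is empty; per-population statistics are undefined")
  pref <- integer(n) + 2L
  pref[sample.int(n)[seq_len(n1)]] <- 1L

  beh <- integer(n)
  idx1 <- which(pref == 1L)
  idx2 <- which(pref == 2L)
  beh[idx1] <- 2L
  beh[idx2] <- 1L
  k1 <- round(params$p1 * length(idx1))
  k2 <- round(params$p2 * length(idx2))
  if (length(idx1) > 0 && k1 > 0)
    beh[idx1[sample.int(length(idx1))[seq_len(k1)]]] <- 1L
  if (length(idx2) > 0 && k2 > 0)
    beh[idx2[sample.int(length(idx2))[seq_len(k2)]]] <- 2L

  dims <- c(params$n_rows, params$n_cols)
  structure(list(
    preference = matrix(pref, dims[1], dims[2]),
    behavior = matrix(beh, dims[1], dims[2]),
    last_payoff = matrix(0, dims[1], dims[2]),
    cumulative_payoff = matrix(0, dims[1], dims[2]),
    t = 0L), class = "norms_grid")
}

#' @export
print.norms_grid <- function(x, ...) {
  n <- length(x$behavior)
  cat(sprintf("norms_grid: %d x %d torus at t = %d\n",
              nrow(x$behavior), ncol(x$behavior), x$t))
  cat(sprintf("  share showing behavior 1: %.3f\n", mean(x$behavior == 1)))
  cat(sprintf("  share showing preferred behavior: %.3f\n",
              mean(x$behavior == x$preference)))
  invisible(x)
}

#' Behavior and preference shares of a grid state
#'
#' @param state A `norms_grid`.
#' @return Named numeric vector with `share_b1`, `share_b2`,
#'   `share_preferred`.
#' @export
grid_shares <- function(state) {
  c(share_b1 = mean(state$behavior == 1L),
    share_b2 = mean(state$behavior == 2L),
    share_preferred = mean(state$behavior == state$preference))
}
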
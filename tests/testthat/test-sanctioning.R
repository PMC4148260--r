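# Peer punishment: triggers, solvency guard, adaptive cost, typology.

test_that("behavior- and preference-based triggers fire as defined", {
  pref <- matrix(c(1L, 2L), 4, 4)
  beh <- matrix(2L, 4, 4)
  beh[1, 1] <- 1L
  g <- manual_grid(pref, beh,
                   cumulative_payoff = matrix(10, 4, 4))

  bmode <- punishment_config("behavior", C = 0.5, k = 3)
  pmode <- punishment_config("preference", C = 0.5, k = 3)

  # identical behavior: no behavior-based punishment
  expect_false(punish_decision(g, c(2, 1), c(2, 2), bmode)$trigger)
  # different behavior: punish, fine = k * C
  dec <- punish_decision(g, c(1, 1), c(2, 1), bmode)
  expect_true(dec$trigger)
  expect_equal(dec$fine, 1.5)
  # preference-based: ego (prefers 1, shows 2) punishes alter showing 2,
  # even though ego shows the same behavior
  expect_true(punish_decision(g, c(1, 2), c(2, 2), pmode)$trigger)
  # but not a partner who complies with ego's preference
  expect_false(punish_decision(g, c(1, 2), c(1, 1), pmode)$trigger)
})

test_that("the solvency guard vetoes unaffordable sanctions", {
  pref <- matrix(1L, 3, 3); beh <- matrix(1L, 3, 3); beh[2, 2] <- 2L
  g <- manual_grid(pref, beh, cumulative_payoff = matrix(0.3, 3, 3))
  bmode <- punishment_config("behavior", C = 0.5, k = 3)
  expect_false(punish_decision(g, c(1, 1), c(2, 2), bmode)$trigger)
  g$cumulative_payoff[1, 1] <- 0.5  # exactly affordable
  expect_true(punish_decision(g, c(1, 1), c(2, 2), bmode)$trigger)
})

test_that("adaptive group pressure follows the closed-form cost curve", {
  expect_equal(adaptive_cost(0, C0 = 1), 1)
  expect_equal(adaptive_cost(1, C0 = 1), 0)
  expect_equal(adaptive_cost(0.5, C0 = 1), 49 / 256)
  expect_equal(adaptive_cost(0.5, C0 = 2), 2 * 49 / 256)
  expect_error(adaptive_cost(1.5), "\\[0, 1\\]")
  # continuous and strictly decreasing on [0, 1]
  mesh <- seq(0, 1, length.out = 2001)
  vals <- adaptive_cost(mesh, C0 = 1)
  expect_true(all(diff(vals) < 0))
  expect_lt(max(abs(diff(vals))), 0.01)
})

test_that("the local non-conformity fraction counts range-R neighbors", {
  beh <- matrix(1L, 5, 5)
  g <- manual_grid(matrix(1L, 5, 5), beh)
  expect_equal(nonconforming_fraction(g, c(3, 3), R = 1), 0)
  g$behavior[2, 2] <- 2L; g$behavior[4, 4] <- 2L
  expect_equal(nonconforming_fraction(g, c(3, 3), R = 1), 0.25)
  g$behavior[] <- 2L; g$behavior[3, 3] <- 1L
  expect_equal(nonconforming_fraction(g, c(3, 3), R = 1), 1)
  # adaptive trigger with N = 1 carries zero cost and fine
  gg <- manual_grid(matrix(1L, 5, 5), g$behavior,
                    cumulative_payoff = matrix(5, 5, 5))
  dec <- punish_decision(gg, c(3, 3), c(3, 4),
                         punishment_config("adaptive", k = 3, C0 = 1),
                         R = 1)
  expect_true(dec$trigger)
  expect_equal(dec$cost, 0)
  expect_equal(dec$fine, 0)
})

test_that("the four punishment types are classified as in the typology", {
  pref <- matrix(c(2L, 1L, 1L, 2L), 2, 2)
  beh <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  g <- manual_grid(pref, beh)
  # behavior-based: punisher prefers 2 but shows 1, punishes behavior 2
  expect_equal(classify_punishment(g, c(1, 1), c(1, 2), "behavior"),
               "hypocritical")
  # behavior-based: punisher prefers and shows 1, punishes behavior 2
  expect_equal(classify_punishment(g, c(2, 1), c(2, 2), "behavior"),
               "sincere")
  # preference-based: punisher prefers 1, shows 2, punishes behavior 2
  expect_equal(classify_punishment(g, c(1, 2), c(2, 2), "preference"),
               "hypocritical")
  # preference-based: punisher prefers 1, shows 1, punishes behavior 2
  expect_equal(classify_punishment(g, c(2, 1), c(1, 2), "preference"),
               "sincere")
  # adaptive mode classifies like behavior-based
  expect_equal(classify_punishment(g, c(1, 1), c(1, 2), "adaptive"),
               "hypocritical")
})

test_that("sanctions debit the punisher's cost and the punishee's fine", {
  g <- uniform_grid(3)
  g$last_payoff[1, 1] <- 1.2; g$last_payoff[2, 2] <- 0
  g2 <- apply_punishment(g, c(1, 1), c(2, 2), cost = 0.5, fine = 1.5)
  expect_equal(g2$last_payoff[1, 1], 0.7)
  expect_equal(g2$last_payoff[2, 2], -1.5)  # fines may go negative
  expect_equal(g2$cumulative_payoff[1, 1], -0.5)
  expect_equal(g2$cumulative_payoff[2, 2], -1.5)
})

test_that("payoff accounting balances over a punished run", {
  p <- sim_params(n_rows = 10, n_cols = 10, R = 2, T = 20, B = 1.2,
                  S = 0.6, p1 = 0.5, p2 = 0.5)
  run <- run_simulation(p, punishment_config("behavior", L = 1.5, k = 3),
                        seed = 11, record_events = TRUE)
  expect_equal(run$events$fine, run$punish$k * run$events$cost)
  expect_equal(sum(run$state$cumulative_payoff),
               run$total_gross_payoff - sum(run$events$cost) -
                 sum(run$events$fine))
})

test_that("behavior-based pressure raises conformity with the level L", {
  share_b2 <- sapply(c(0, 3), function(L) {
    pun <- if (L == 0) punishment_config("none")
           else punishment_config("behavior", L = L, k = 3)
    mean(sapply(1:3, function(rep) {
      run <- run_simulation(
        sim_params(A = 1, B = 1.2, S = 0.8, R = 2, r = 0.01, p1 = 0.5,
                   p2 = 0.5, n_rows = 30, n_cols = 30, T = 200),
        pun, seed = derive_seed(21, round(L), rep))
      grid_shares(run$state)["share_b2"]
    }))
  })
  expect_gt(share_b2[1], 0.15)  # coexistence without sanctions
  expect_lt(share_b2[2], 0.05)  # strong sanctions enforce the norm
})
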
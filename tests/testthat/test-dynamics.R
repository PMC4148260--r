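# Random-sequential update: interaction, imitation, noise, full steps.

test_that("partner choice is uniform over the range-R neighborhood", {
  g <- uniform_grid(10)
  set.seed(1)
  draws <- t(replicate(10000, choose_partner(g, c(5, 5), R = 1)))
  expect_true(all(pmax(abs(draws[, 1] - 5), abs(draws[, 2] - 5)) == 1))
  freq <- table(paste(draws[, 1], draws[, 2])) / nrow(draws)
  expect_equal(length(freq), 8)
  expect_true(all(abs(freq - 0.125) < 0.02))
  # determinism under a fixed seed
  set.seed(7); a <- choose_partner(g, c(2, 2), R = 2)
  set.seed(7); b <- choose_partner(g, c(2, 2), R = 2)
  expect_identical(a, b)
})

test_that("role models are uniform among same-preference neighbors", {
  pref <- matrix(2L, 5, 5)
  pref[3, 3] <- 1L  # focal is the only member of population 1 around
  g <- manual_grid(pref, matrix(1L, 5, 5))
  set.seed(1)
  expect_null(choose_role_model(g, c(3, 3), R = 1))

  pref[2, 2] <- 1L  # exactly one eligible neighbor
  g <- manual_grid(pref, matrix(1L, 5, 5))
  set.seed(1)
  expect_equal(unname(choose_role_model(g, c(3, 3), R = 1)), c(2, 2))

  # single population: every neighbor is eligible
  g <- uniform_grid(5)
  set.seed(1)
  rm <- choose_role_model(g, c(3, 3), R = 1)
  expect_equal(max(abs(rm - c(3, 3))), 1)
})

test_that("imitation is proportional to the payoff difference, clipped", {
  p <- sim_params(A = 1, B = 0.5, n_rows = 5, n_cols = 5, R = 1)
  base <- uniform_grid(5)
  base$behavior[2, 2] <- 2L

  prob_switch <- function(model_payoff, n = 4000) {
    g <- base
    g$last_payoff[2, 2] <- model_payoff  # role model's last payoff
    g$last_payoff[3, 3] <- 0
    mean(replicate(n,
      imitation_update(g, c(3, 3), c(2, 2), p)$switched))
  }
  set.seed(5)
  expect_equal(prob_switch(1.5, n = 200), 1)        # difference = A + B
  expect_equal(prob_switch(0.5), 1 / 3, tolerance = 0.1)  # 0.5 / 1.5
  expect_equal(prob_switch(3, n = 200), 1)          # clipped above A + B
  # lower or equal payoff: sticks with the previous behavior
  g <- base; g$last_payoff[3, 3] <- 2
  set.seed(5)
  expect_false(imitation_update(g, c(3, 3), c(2, 2), p)$switched)
  g$last_payoff[2, 2] <- 2  # exact tie
  expect_false(imitation_update(g, c(3, 3), c(2, 2), p)$switched)
  expect_false(imitation_update(g, c(3, 3), NULL, p)$switched)
})

test_that("random strategy flipping toggles behavior at rate r", {
  g <- uniform_grid(4)
  set.seed(1)
  expect_false(noise_update(g, c(1, 1), r = 0)$flipped)
  out <- noise_update(g, c(1, 1), r = 1)
  expect_true(out$flipped)
  expect_equal(out$state$behavior[1, 1], 2L)
  expect_equal(out$state$preference[1, 1], 1L)  # preference untouched
  set.seed(2)
  flips <- replicate(1e5, noise_update(g, c(2, 2), r = 0.01)$flipped)
  expect_equal(mean(flips), 0.01, tolerance = 0.2)
})

test_that("a step performs N/2 rounds and reaches absorbing states", {
  # single fully committed population without noise never changes
  p <- tiny_params(S = 1, p1 = 1, r = 0)
  set.seed(1)
  st <- suppressWarnings(init_grid(p))  # single population warns
  out <- advance_step(st, p)
  expect_equal(out$metrics$share_preferred, 1)
  expect_equal(out$metrics$t, 1)
  expect_true(all(out$state$behavior == 1L))

  # metrics recomputed from the grid match direct counts
  p2 <- tiny_params(S = 0.5, p1 = 0.7, p2 = 0.6)
  set.seed(2)
  st2 <- init_grid(p2)
  out2 <- advance_step(st2, p2)
  expect_equal(out2$metrics$share_b1, mean(out2$state$behavior == 1))
  expect_equal(out2$metrics$share_preferred,
               mean(out2$state$behavior == out2$state$preference))
  expect_equal(out2$metrics$mean_payoff, mean(out2$state$last_payoff))
})

test_that("compiled and reference engines give bit-identical runs", {
  p <- sim_params(n_rows = 8, n_cols = 8, R = 1, T = 6, B = 1.1,
                  S = 0.5, p1 = 1, p2 = 1)
  for (pun in list(punishment_config("none"),
                   punishment_config("behavior", L = 1.5, k = 3),
                   punishment_config("preference", C = 0.2, k = 2),
                   punishment_config("adaptive", k = 3, C0 = 1))) {
    a <- run_simulation(p, pun, seed = 7, engine = "cpp",
                        record_events = TRUE)
    b <- run_simulation(p, pun, seed = 7, engine = "r",
                        record_events = TRUE)
    expect_identical(a$state$behavior, b$state$behavior)
    expect_equal(a$state$cumulative_payoff, b$state$cumulative_payoff)
    expect_equal(a$timeseries, b$timeseries)
    expect_equal(nrow(a$events), nrow(b$events))
    expect_equal(a$total_gross_payoff, b$total_gross_payoff)
  }
})

test_that("preference counts are conserved across steps", {
  p <- sim_params(n_rows = 12, n_cols = 12, R = 2, T = 30, S = 0.7,
                  B = 1.2, r = 0.05)
  run <- run_simulation(p, punishment_config("behavior", L = 2, k = 3),
                        seed = 3)
  expect_equal(sum(run$state$preference == 1), round(0.7 * 144))
})

test_that("coexistence holds when the preference benefit beats conformity", {
  # B > A, balanced populations, full commitment: agents keep their
  # preferred behavior up to noise
  p <- sim_params(A = 1, B = 1.2, S = 0.5, p1 = 1, p2 = 1, R = 10,
                  r = 0.01, n_rows = 30, n_cols = 30, T = 100)
  run <- run_simulation(p, seed = 4)
  expect_true(all(run$timeseries$share_preferred > 0.9))
  expect_equal(classify_outcome(run$state), "coexistence")
})

test_that("relabeling populations mirrors the trajectory statistically", {
  pa <- sim_params(A = 1, B = 0.5, S = 0.35, p1 = 0.8, p2 = 0.3, R = 5,
                   r = 0.01, n_rows = 24, n_cols = 24, T = 60)
  pb <- sim_params(A = 1, B = 0.5, S = 0.65, p1 = 0.3, p2 = 0.8, R = 5,
                   r = 0.01, n_rows = 24, n_cols = 24, T = 60)
  sa <- rowMeans(sapply(1:6, function(i)
    run_simulation(pa, seed = i)$timeseries$share_b1))
  sb <- rowMeans(sapply(1:6, function(i)
    run_simulation(pb, seed = 100 + i)$timeseries$share_b2))
  expect_lt(mean(abs(sa - sb)), 0.06)
})

test_that("more noise means more erroneous deviants in coexistence", {
  dev <- sapply(c(0.005, 0.04, 0.15), function(r) {
    p <- sim_params(A = 1, B = 1.2, S = 0.5, p1 = 1, p2 = 1, R = 5,
                    r = r, n_rows = 24, n_cols = 24, T = 60)
    run <- run_simulation(p, seed = 8)
    mean(run$timeseries$share_preferred[31:60])
  })
  expect_true(all(diff(dev) < 0))
})
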
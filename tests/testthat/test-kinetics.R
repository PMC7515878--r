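# closed-form helpers for tiny systems
two_state_occupancy <- function(p) {
  # n = 2: empty vs single-bond state; bonded probability from the
  # Boltzmann weights exp(-beta H)
  Hb <- p$phi[["e"]] + p$k_B * p$T
  w <- exp(-Hb / (p$k_B * p$T))
  w / (1 + w)
}

test_that("transition rates follow the logistic rate law", {
  # a toggle with zero energy difference proceeds at half the collision rate
  p0 <- model_params(c(e = -1, `2s` = 0, NSP1 = 0, NSP2 = 0, ESP0 = 0,
                       ESP1 = 0, C5 = 0, C6 = 0, C7 = 0), A = 3)
  expect_equal(transition_rate(aggregation_graph(2), 1, 2, p0), 1.5)
  # beta * dH = log 3 gives A / 4
  p3 <- model_params(c(e = log(3) - 1, `2s` = 0, NSP1 = 0, NSP2 = 0,
                       ESP0 = 0, ESP1 = 0, C5 = 0, C6 = 0, C7 = 0), A = 2)
  expect_equal(transition_rate(aggregation_graph(2), 1, 2, p3), 0.5)
  # rates always lie strictly inside (0, A)
  p <- default_params(A = 1.7)
  set.seed(21)
  for (rep in 1:20) {
    g <- random_graph(5, 0.5)
    uv <- sample(5, 2)
    r <- transition_rate(g, uv[1], uv[2], p)
    expect_gt(r, 0); expect_lt(r, 1.7)
  }
})

test_that("uphill rates approach the Arrhenius law within 1% for beta dH >= 7", {
  for (bdH in c(7, 9, 12)) {
    p <- model_params(c(e = bdH - 1, `2s` = 0, NSP1 = 0, NSP2 = 0, ESP0 = 0,
                        ESP1 = 0, C5 = 0, C6 = 0, C7 = 0), A = 1)
    r <- transition_rate(aggregation_graph(3), 1, 2, p)
    arr <- exp(-bdH)
    expect_lt(abs(r - arr) / arr, 0.01)
  }
})

test_that("forward/backward rates satisfy the detailed-balance ratio identity", {
  p <- default_params(T = 1.4, A = 2.2)
  beta <- 1 / (p$k_B * p$T)
  set.seed(31)
  for (rep in 1:25) {
    g <- random_graph(6, 0.4)
    uv <- sample(6, 2)
    dH <- sum(hamiltonian_coefficients(p) * change_stats(g, uv[1], uv[2]))
    fwd <- transition_rate(g, uv[1], uv[2], p)
    bwd <- transition_rate(toggle_edge(g, uv[1], uv[2]), uv[1], uv[2], p)
    expect_equal(fwd / bwd, exp(-beta * dH), tolerance = 1e-12)
  }
})

test_that("the transition distribution is a proper distribution over Hamming neighbours", {
  p <- default_params()
  expect_error(transition_distribution(aggregation_graph(1), p), "n < 2")
  # n = 2: the unique neighbour takes all the probability
  td2 <- transition_distribution(aggregation_graph(2), p)
  expect_equal(td2$probs, 1)
  # empty graph with homogeneous parameters: all additions equiprobable
  td <- transition_distribution(aggregation_graph(6), p)
  expect_equal(nrow(td$dyads), choose(6, 2))
  expect_equal(sum(td$probs), 1, tolerance = 1e-12)
  expect_equal(td$exit_rate, sum(td$rates))
  expect_equal(td$probs, rep(1 / 15, 15))
  # generic state: probabilities still normalized
  set.seed(41)
  g <- random_graph(6, 0.5)
  tdg <- transition_distribution(g, p)
  expect_equal(sum(tdg$probs), 1, tolerance = 1e-12)
  expect_equal(tdg$rates[1], transition_rate(g, 1, 2, p))
})

test_that("trajectories start empty at time zero with strictly increasing single-toggle events", {
  p <- default_params()
  tr <- simulate_fibrillization(6, p, max_events = 400, seed = 9)
  expect_s3_class(tr, "fibril_trajectory")
  expect_equal(trajectory_graph(tr, 0)$edges, matrix(integer(0), ncol = 2))
  expect_true(all(diff(tr$events$time) > 0))
  expect_gt(tr$events$time[1], 0)
  expect_true(all(tr$events$action %in% c("add", "del")))
  # replay one event at a time: consecutive states differ by one bond
  for (i in c(1, 57, 300)) {
    g0 <- trajectory_graph(tr, i - 1)
    g1 <- trajectory_graph(tr, i)
    expect_equal(abs(nrow(g1$edges) - nrow(g0$edges)), 1)
  }
})

test_that("identical seeds reproduce trajectories; different seeds do not", {
  p <- default_params()
  a <- simulate_fibrillization(5, p, max_events = 500, seed = 4)
  b <- simulate_fibrillization(5, p, max_events = 500, seed = 4)
  expect_identical(a$events, b$events)
  c <- simulate_fibrillization(5, p, max_events = 500, seed = 5)
  expect_false(identical(a$events, c$events))
})

test_that("incremental rate bookkeeping reproduces naive recomputation event for event", {
  p <- dendrite_params()
  inc <- simulate_fibrillization(30, p, max_events = 1000, seed = 13,
                                 method = "incremental")
  nai <- simulate_fibrillization(30, p, max_events = 1000, seed = 13,
                                 method = "naive")
  expect_identical(inc$events, nai$events)
  expect_identical(inc$end_time, nai$end_time)
})

test_that("max_time stopping yields a trajectory bounded by the requested time", {
  p <- default_params()
  tr <- simulate_fibrillization(5, p, max_time = 3, seed = 6)
  expect_lte(max(tr$events$time), 3)
  expect_lte(tr$end_time, 3)
})

test_that("n = 2 time-weighted occupancy matches the two-state Boltzmann weight", {
  p <- model_params(c(e = -1.4, `2s` = 0, NSP1 = 0, NSP2 = 0, ESP0 = 0,
                      ESP1 = 0, C5 = 0, C6 = 0, C7 = 0))
  tr <- simulate_fibrillization(2, p, max_events = 2e4, seed = 17)
  ev <- tr$events
  dwell <- diff(c(0, ev$time))
  # the state before event i has a bond iff i is even (alternating chain)
  bonded_before <- (seq_along(dwell) %% 2L) == 0L
  occ <- sum(dwell[bonded_before]) / sum(dwell)
  target <- two_state_occupancy(p)
  # 3 standard errors using an effective sample size of bond sojourns
  se <- sqrt(target * (1 - target) / (nrow(ev) / 2))
  expect_lt(abs(occ - target), 3 * se + 0.01)
})

test_that("sojourn times in a held state are exponential with mean 1/exit rate", {
  p0 <- model_params(c(e = -1, `2s` = 0, NSP1 = 0, NSP2 = 0, ESP0 = 0,
                       ESP1 = 0, C5 = 0, C6 = 0, C7 = 0))
  # flat exponent: every state has exit rate C(n,2) * A / 2
  n <- 4
  tr <- simulate_fibrillization(n, p0, max_events = 2e4, seed = 23)
  waits <- diff(c(0, tr$events$time))
  R <- choose(n, 2) / 2
  expect_equal(mean(waits), 1 / R,
               tolerance = 3 / sqrt(length(waits)) + 0.01)
  # exponential shape: variance ~ mean^2
  expect_equal(stats::sd(waits) / mean(waits), 1, tolerance = 0.05)
})
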
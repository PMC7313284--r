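test_that("supervised fitting reproduces hand-computed bigram estimates", {
  obs <- observation_sequence(scores = matrix(0, 4, 1))
  m0 <- fit_hmm(obs, c(1, 1, 2, 2), smoothing = 0)
  expect_equal(m0$A, rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(m0$pi, c(0.5, 0.5))

  m1 <- fit_hmm(obs, c(1, 1, 2, 2), smoothing = 1)
  expect_equal(m1$A, rbind(c(0.5, 0.5), c(1 / 3, 2 / 3)))
  expect_equal(rowSums(m1$A), c(1, 1), tolerance = 1e-12)
  expect_equal(sum(m1$pi), 1, tolerance = 1e-12)
})

test_that("per-state Gaussians recover constant observations with floored variance", {
  sc <- matrix(c(2, 2, -1, -1, -1), ncol = 1)
  m <- fit_hmm(observation_sequence(scores = sc), c(1, 1, 2, 2, 2), smoothing = 1)
  expect_equal(drop(m$means), c(2, -1))
  expect_equal(drop(m$vars), c(1e-6, 1e-6))
  expect_error(fit_hmm(observation_sequence(scores = sc), c(1, 1, 1, 1, 1),
                       n_states = 2), "never occurs")
})

test_that("categorical emissions are smoothed per state", {
  obs <- observation_sequence(est_labels = c(1, 1, 2, 1), n_classes = 2)
  m <- fit_hmm(obs, c(1, 1, 1, 2), smoothing = 1)
  # state 1 saw labels (1,1,2); state 2 saw (1)
  expect_equal(m$emit_cat, rbind(c(3 / 5, 2 / 5), c(2 / 3, 1 / 3)))
})

test_that("subject boundaries break the bigram chain", {
  obs <- observation_sequence(scores = matrix(0, 4, 1), subjects = c(1, 1, 2, 2))
  expect_warning(m <- fit_hmm(obs, c(1, 2, 2, 2), smoothing = 0),
                 "single observation")
  # cross-boundary 2->2 not counted: transitions are 1->2 and 2->2 (once)
  expect_equal(m$trans_counts, rbind(c(0, 1), c(0, 1)))
})

test_that("log joint matches the term-by-term product on small instances", {
  for (seed in 1:5) {
    N <- sample(2:3, 1)
    m <- make_random_hmm(N, 2, seed)
    obs <- random_obs(N, 2, 5, seed)
    states <- sample.int(N, 5, replace = TRUE)
    # independent direct computation
    dens <- 1
    for (t in 1:5) {
      dens <- dens * prod(stats::dnorm(obs$scores[t, ], m$means[states[t], ],
                                       sqrt(m$vars[states[t], ])))
      dens <- dens * m$emit_cat[states[t], obs$est_labels[t]]
    }
    chain <- m$pi[states[1]]
    for (t in 2:5) chain <- chain * m$A[states[t - 1], states[t]]
    expect_equal(log_joint(m, obs, states), log(dens * chain), tolerance = 1e-9)
  }
})

test_that("single observations and impossible transitions behave as documented", {
  m <- make_random_hmm(2, 1, 3)
  obs1 <- observation_sequence(scores = matrix(0.3), est_labels = 1, n_classes = 2)
  expect_equal(log_joint(m, obs1, 1),
               log(m$pi[1]) + dnorm(0.3, m$means[1, 1], sqrt(m$vars[1, 1]), log = TRUE) +
                 log(m$emit_cat[1, 1]))
  m$A[1, 2] <- 0; m$A[1, 1] <- 1
  obs2 <- observation_sequence(scores = matrix(c(0, 0), 2), est_labels = c(1, 1),
                               n_classes = 2)
  expect_identical(log_joint(m, obs2, c(1, 2)), -Inf)
})

test_that("uniform transitions reduce Viterbi to framewise emission argmax", {
  N <- 3
  m <- make_random_hmm(N, 2, 7)
  m$A <- matrix(1 / N, N, N)
  m$pi <- rep(1 / N, N)
  obs <- random_obs(N, 2, 40, 7)
  ll <- actiseq:::emission_loglik(m, obs)
  expect_equal(viterbi(m, obs), apply(ll, 1, which.max))

  # uniform A and pi with N = 2, T = 3: chain contribution is 3 * log(1/2)
  m2 <- make_random_hmm(2, 1, 8)
  m2$A <- matrix(0.5, 2, 2); m2$pi <- c(0.5, 0.5)
  obs3 <- random_obs(2, 1, 3, 8)
  ll3 <- actiseq:::emission_loglik(m2, obs3)
  states <- c(2, 1, 2)
  expect_equal(log_joint(m2, obs3, states),
               3 * log(0.5) + sum(ll3[cbind(1:3, states)]), tolerance = 1e-12)
})

test_that("a single state gives a constant decoded sequence", {
  m <- make_random_hmm(1, 2, 9)
  m$A <- matrix(1, 1, 1); m$pi <- 1; m$emit_cat <- matrix(1, 1, 1)
  obs <- observation_sequence(scores = matrix(rnorm(10), 5),
                              est_labels = rep(1, 5), n_classes = 1)
  expect_equal(viterbi(m, obs), rep(1L, 5))
})

test_that("exact ties resolve to the same path in Viterbi and the oracle", {
  m <- make_random_hmm(2, 1, 10)
  m$A <- matrix(0.5, 2, 2); m$pi <- c(0.5, 0.5)
  m$means <- matrix(0, 2, 1); m$vars <- matrix(1, 2, 1)
  m$emit_cat <- matrix(0.5, 2, 2)        # emissions identical across states
  obs <- observation_sequence(scores = matrix(rnorm(4), 4),
                              est_labels = c(1, 2, 1, 2), n_classes = 2)
  v <- viterbi(m, obs)
  expect_equal(v, rep(1L, 4))            # lexicographically smallest path
  expect_equal(brute_force_decode(m, obs), v)
})

test_that("Viterbi matches exhaustive enumeration on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    N <- sample(2:4, 1); Tn <- sample(2:7, 1)
    m <- make_random_hmm(N, 2, seed * 13)
    obs <- random_obs(N, 2, Tn, seed * 13)
    v <- viterbi(m, obs)
    b <- brute_force_decode(m, obs)
    expect_equal(v, b)
    expect_equal(log_joint(m, obs, v), log_joint(m, obs, b), tolerance = 1e-9)
  }
})

test_that("the Viterbi path beats random paths", {
  m <- make_random_hmm(3, 2, 31)
  obs <- random_obs(3, 2, 12, 31)
  v <- viterbi(m, obs)
  best <- log_joint(m, obs, v)
  set.seed(32)
  for (i in 1:1000) {
    expect_gte(best, log_joint(m, obs, sample.int(3, 12, replace = TRUE)))
  }
})

test_that("multi-subject observations decode independently", {
  m <- make_random_hmm(3, 2, 33)
  sc <- matrix(rnorm(24), 12)
  el <- sample.int(3, 12, replace = TRUE)
  joint <- observation_sequence(sc, el, 3, subjects = rep(1:2, each = 6))
  a <- observation_sequence(sc[1:6, ], el[1:6], 3)
  b <- observation_sequence(sc[7:12, ], el[7:12], 3)
  expect_equal(viterbi(m, joint), c(viterbi(m, a), viterbi(m, b)))
})

test_that("transition structure is recovered from a long simulated chain", {
  sim <- simulate_activity_data(n_classes = 4, n_features = 4, len = 20000,
                                stickiness = 0.9, separation = 2, seed = 41)
  m <- fit_hmm(observation_sequence(scores = sim$x), sim$labels, smoothing = 1)
  expect_lt(max(abs(m$A - sim$transition)), 0.02)
})
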
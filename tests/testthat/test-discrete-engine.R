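test_that("likelihood message applies the transpose-normalized mapping", {
  # identity likelihood: log one-hot after the floor
  msg <- likelihood_message(diag(3), 2L)
  expect_equal(which.max(msg), 2L)
  expect_equal(msg[2], 0)
  expect_equal(msg[-2], rep(-16, 2))
  # uniform likelihood carries no information
  expect_equal(diff(range(likelihood_message(matrix(0.5, 2, 2), 1L))), 0)
  # asymmetric case, computed by hand from the normalization convention
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  expect_equal(likelihood_message(A, 1L), log(c(0.9, 0.1)), tolerance = 1e-12)
  expect_error(likelihood_message(diag(2), 5L), "out of range")
})

test_that("forward and backward messages act as the stated matrix products", {
  s <- c(0.2, 0.3, 0.5)
  expect_equal(forward_message(diag(3), s), log(s), tolerance = 1e-12)
  expect_equal(diff(range(forward_message(matrix(1 / 3, 3, 3), s))), 0)
  P <- diag(3)[, c(2, 3, 1)]  # cyclic permutation
  expect_equal(which.max(forward_message(P, c(1, 0, 0))), 2L)
  expect_equal(which.max(backward_message(P, c(0, 1, 0))), 1L)
  expect_equal(diff(range(backward_message(matrix(1 / 3, 3, 3), s))), 0)
  expect_equal(diff(range(backward_message(P, rep(1 / 3, 3)))), 0)
})

test_that("fixed-point posteriors are exact with uniform transitions", {
  set.seed(21)
  for (r in 1:20) {
    m <- uniform_B_model()
    tau_obs <- sample(seq_len(m$T), 1)
    obs <- vector("list", m$T)
    obs[[tau_obs]] <- sample(seq_len(m$n_out[1]), 1)
    s <- state_update_fixed_point(m, obs)
    oracle <- enumerate_posterior(m, obs)
    expect_lt(max(abs(s - oracle$marginals)), 1e-10)
  }
})

test_that("fixed point with no observations propagates the prior", {
  # exact in the uniform-transition regime (backward messages carry no
  # information there); with generic transitions the scheme is loopy and
  # approximate, as the smoothed no-evidence marginals are slightly biased
  set.seed(22)
  m <- uniform_B_model(n = 3, T = 3)
  s <- state_update_fixed_point(m, vector("list", 3))
  oracle <- enumerate_posterior(m, vector("list", 3))
  expect_lt(max(abs(s - oracle$marginals)), 1e-8)
  expect_equal(s[, 1], as.numeric(m$D[[1]]), tolerance = 1e-8)
  # generic transitions: the forward-propagated prior is still the dominant
  # structure (argmax agreement with the exact marginals)
  m2 <- random_small_model(n = 3, T = 3, n_pol = 1)
  s2 <- state_update_fixed_point(m2, vector("list", 3))
  o2 <- enumerate_posterior(m2, vector("list", 3))
  expect_lt(max(abs(s2 - o2$marginals)), 0.1)
})

test_that("deterministic chains are recovered one-hot from full observations", {
  m <- permutation_model(n = 3, T = 4)
  true_seq <- c(1L, 2L, 3L, 1L)
  s <- state_update_fixed_point(m, as.list(true_seq))
  expect_lt(max(abs(s - sapply(true_seq, one_hot_vec, n = 3))), 1e-8)
})

test_that("gradient scheme agrees with the fixed point where both are exact", {
  set.seed(23)
  m <- uniform_B_model(n = 3, T = 3, n_out = 3)
  obs <- list(NULL, 2L, NULL)
  fp <- state_update_fixed_point(m, obs)
  for (msgs in c("sum_product", "variational")) {
    g <- state_update_gradient(m, obs, iterations = 400, messages = msgs)
    expect_lt(max(abs(g$s - fp)), 1e-6)
  }
})

test_that("prediction errors vanish (softmax gauge) at the stationary point", {
  set.seed(24)
  m <- random_small_model(n = 3, T = 3, n_pol = 1)
  obs <- random_observations(m)
  g <- state_update_gradient(m, obs, iterations = 4000, step = 0.25)
  # converged: error components equal within each epoch (pure gauge)
  gauge <- apply(g$eps, 2, function(e) diff(range(e)))
  expect_lt(max(gauge), 1e-6)
  # one further iteration leaves expectations unchanged
  g2 <- state_update_gradient(m, obs, iterations = 1, init = g$s)
  expect_lt(max(abs(g2$s - g$s)), 1e-6)
})

test_that("variational gradient flow never increases free energy", {
  set.seed(25)
  for (r in 1:30) {
    m <- random_small_model()
    obs <- random_observations(m)
    for (p in seq_len(m$n_policies)) {
      g <- state_update_gradient(m, obs, p, messages = "variational")
      expect_true(all(diff(g$F_trace) <= 1e-9))
    }
  }
})

test_that("expected outcomes are the likelihood applied to expectations", {
  s <- c(0.25, 0.75)
  expect_equal(expected_outcomes(diag(2), s)[[1]], s)
  A <- normalize_columns(matrix(c(1, 0, 0, 0, 1, 1), 3, 2))
  expect_equal(expected_outcomes(A, c(1, 0))[[1]], c(1, 0, 0))
  expect_equal(expected_outcomes(A, c(0.5, 0.5))[[1]], rowMeans(A))
})

test_that("expected free energy decomposes into risk plus ambiguity", {
  # zero ambiguity, preference-matched: exactly zero
  m <- discrete_model(A = diag(2), B = array(diag(2), c(2, 2, 1)),
                      C = ln_safe(c(0.7, 0.3)), D = c(0.7, 0.3), T = 1)
  s <- matrix(c(0.7, 0.3), 2, 1)
  expect_identical(expected_free_energy(m, s), 0)
  # hand-computed KL: o = (1,0) against uniform preferences is ln 2
  m2 <- discrete_model(A = diag(2), B = array(diag(2), c(2, 2, 1)),
                       C = log(c(0.5, 0.5)), D = c(0.5, 0.5), T = 1)
  expect_equal(expected_free_energy(m2, matrix(c(1, 0), 2, 1)), log(2),
               tolerance = 1e-9)
  # uniform predicted outcomes under uniform preferences: zero risk
  expect_equal(expected_free_energy(m2, matrix(0.5, 2, 1)), 0,
               tolerance = 1e-12)
})

test_that("policy posterior is a softmax of negative expected free energy", {
  expect_equal(policy_posterior(c(1, 1)), c(0.5, 0.5))
  expect_equal(policy_posterior(c(log(2), 0)), c(1 / 3, 2 / 3),
               tolerance = 1e-12)
  expect_equal(policy_posterior(c(3, -1, 2), gamma = 0), rep(1 / 3, 3))
  # gauge invariance: adding a constant to G changes nothing
  set.seed(26)
  G <- stats::rnorm(4)
  expect_equal(policy_posterior(G), policy_posterior(G + 5), tolerance = 1e-12)
  expect_error(policy_posterior(c(1, NaN)), "non-finite")
})

test_that("Bayesian model averaging is the posterior-weighted mixture", {
  s1 <- c(0.9, 0.1)
  s2 <- c(0.2, 0.8)
  expect_equal(bayesian_model_average(list(s1, s1), c(0.3, 0.7)), s1)
  expect_equal(bayesian_model_average(list(s1, s2), c(1, 0)), s1)
  expect_equal(bayesian_model_average(list(s1, s2), c(1 / 3, 2 / 3)),
               (s1 + 2 * s2) / 3, tolerance = 1e-12)
})

test_that("action selection marginalizes policies and breaks ties downward", {
  pol <- array(c(2L, 2L), c(1, 2, 1))
  expect_equal(select_action(c(0.9, 0.1), pol, 1), 2L)
  pol2 <- array(c(1L, 2L), c(1, 2, 1))
  expect_equal(select_action(c(0.7, 0.3), pol2, 1), 1L)
  # exact tie between actions 3 and 1: lowest index wins
  pol3 <- array(c(3L, 1L), c(1, 2, 1))
  expect_equal(select_action(c(0.5, 0.5), pol3, 1), 1L)
})

test_that("the generative process is sampled reproducibly and faithfully", {
  m <- permutation_model(n = 3, T = 3)
  s1 <- rng_stream(42)
  s2 <- rng_stream(42)
  a <- step_process(c(1L), integer(0), m, s1)
  b <- step_process(c(1L), integer(0), m, s2)
  expect_identical(a, b)
  # deterministic process: deterministic trajectory
  expect_identical(a$states, 2L)
  expect_identical(a$outcome, 2L)

  # outcome frequencies match the likelihood within 3 sigma binomial error
  set.seed(31)
  A <- normalize_columns(matrix(stats::runif(6) + 0.2, 2, 3))
  mp <- discrete_model(A = A, B = array(diag(3), c(3, 3, 1)),
                       D = c(1, 0, 0), T = 2)
  stream <- rng_stream(7)
  n_draw <- 1e4
  draws <- vapply(seq_len(n_draw), function(i)
    step_process(c(1L), integer(0), mp, stream)$outcome, integer(1))
  p <- A[1, 1]
  phat <- mean(draws == 1L)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n_draw))
})

test_that("run_trial closes the action-perception cycle", {
  # model = process, deterministic, preference-neutral: posterior tracks truth
  m <- permutation_model(n = 3, T = 4)
  tr <- run_trial(m, m, seed = 3)
  expect_equal(nrow(tr$actions), 3L)           # T - 1 action selections
  for (t in seq_len(tr$T)) {
    expect_equal(which.max(tr$bma[[tr$T]][, t]), as.integer(tr$true_states[1, t]))
  }

  # strong preferences drive predicted outcomes toward the preferred one
  B <- array(0, c(2, 2, 2))
  B[1, , 1] <- 1                                # action 1 -> state 1
  B[2, , 2] <- 1                                # action 2 -> state 2
  pol <- array(c(1L, 2L), c(1, 2, 1))
  mp <- discrete_model(A = diag(2), B = B, D = c(1, 0),
                       C = c(-4, 4), policies = pol, control = 1L, T = 2)
  tr2 <- run_trial(mp, mp, seed = 5)
  expect_equal(tr2$actions[1, 1], 2L)
  pred <- expected_outcomes(mp$A, tr2$bma[[2]][, 2])[[1]]
  risk_final <- sum(pred * (ln_safe(pred) - mp$C[[1]][, 2]))
  prior_pred <- expected_outcomes(mp$A, c(1, 0))[[1]]
  risk_initial <- sum(prior_pred * (ln_safe(prior_pred) - mp$C[[1]][, 2]))
  expect_lt(risk_final, risk_initial)

  # same seed, same record
  expect_equal(run_trial(mp, mp, seed = 9)$outcomes,
               run_trial(mp, mp, seed = 9)$outcomes)
})

test_that("trial records tidy and glance into well-formed tibbles", {
  m <- permutation_model(n = 3, T = 3)
  tr <- run_trial(m, m, seed = 2)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), tr$T * nrow(tr$pi))
  gl <- glance(tr)
  expect_equal(gl$epochs, 3L)
  expect_equal(gl$state_accuracy, 1)
  p <- autoplot(tr)
  expect_s3_class(p, "ggplot")
})
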
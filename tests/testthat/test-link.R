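test_that("descending priors are moment-matched Gaussian mixtures", {
  models <- list(list(eta = -1, Pi = matrix(1)), list(eta = 1, Pi = matrix(1)))
  # one-hot prior returns the selected model's belief exactly
  dp <- descending_prior(models, c(1, 0))
  expect_equal(dp$mean, -1)
  expect_equal(as.numeric(dp$precision), 1)
  # identical models collapse to that model
  same <- list(list(eta = 0.5, Pi = matrix(2)), list(eta = 0.5, Pi = matrix(2)))
  dps <- descending_prior(same, c(0.4, 0.6))
  expect_equal(dps$mean, 0.5)
  expect_equal(as.numeric(dps$precision), 2, tolerance = 1e-12)
  # hand-computed mixture moments: means -1/+1, unit variances, equal weights
  dph <- descending_prior(models, c(0.5, 0.5))
  expect_equal(dph$mean, 0)
  expect_equal(as.numeric(solve(dph$precision)), 2, tolerance = 1e-12)
})

test_that("reduced log evidence has its degenerate zeros", {
  full <- list(mean = c(0, 0), precision = diag(2))
  post <- list(mean = c(0.5, -0.2), precision = diag(3, 2))
  # reduced prior equal to the full prior: exactly zero
  expect_equal(reduced_log_evidence(post, full, full), 0, tolerance = 1e-12)
  # no data (posterior = prior): zero for any admissible equal-precision prior
  red <- list(mean = c(2, 1), precision = diag(2))
  expect_equal(reduced_log_evidence(full, full, red), 0, tolerance = 1e-12)
  # ill-posed reduction (precision deficit) errors
  bad <- list(mean = c(0, 0), precision = diag(0.1, 2))
  narrow_post <- list(mean = c(0, 0), precision = diag(0.5, 2))
  wide_full <- list(mean = c(0, 0), precision = diag(1, 2))
  expect_error(reduced_log_evidence(narrow_post, wide_full, bad), "SPD")
})

test_that("reduced log evidence agrees with the quadrature oracle", {
  set.seed(61)
  for (d in c(1L, 2L)) {
    for (r in 1:10) {
      inst <- random_bmr_instance(d)
      L <- reduced_log_evidence(inst$posterior, inst$full, inst$reduced)
      q_full <- gaussian_evidence_quadrature(inst$full$mean,
                                             solve(inst$full$precision),
                                             inst$loglik)
      q_red <- gaussian_evidence_quadrature(inst$reduced$mean,
                                            solve(inst$reduced$precision),
                                            inst$loglik)
      expect_lt(abs(L - (q_red - q_full)), 1e-6)
    }
  }
})

test_that("evidence accumulation is additive and Riemann-consistent", {
  models <- list(list(eta = -1, Pi = matrix(2)), list(eta = 1, Pi = matrix(2)))
  link <- link_spec(models, c(0.5, 0.5))
  full <- descending_prior(models, link$prior_o)
  snaps <- lapply(seq_len(6), function(k)
    list(mean = -0.8 + 0.05 * k, precision = matrix(3 + k / 10)))
  dt <- 1 / 24
  # two consecutive windows equal their concatenation
  l_two <- accumulate_evidence(
    accumulate_evidence(link, snaps[1:3], dt, full), snaps[4:6], dt, full)
  l_one <- accumulate_evidence(link, snaps, dt, full)
  expect_equal(l_two$L, l_one$L, tolerance = 1e-12)
  expect_equal(l_two$posterior_o, l_one$posterior_o, tolerance = 1e-12)
  # constant integrand: halved steps at doubled dt leave L unchanged
  const <- snaps[c(1, 1, 1, 1)]
  l_fine <- accumulate_evidence(link, const, dt, full)
  l_coarse <- accumulate_evidence(link, const[c(1, 1)], 2 * dt, full)
  expect_equal(l_fine$L, l_coarse$L, tolerance = 1e-12)
})

test_that("with no accumulation the ascending posterior is the descending prior", {
  models <- list(list(eta = -1, Pi = matrix(1)), list(eta = 1, Pi = matrix(1)))
  link <- link_spec(models, c(0.3, 0.7))
  mod <- static_cause_model()
  proc <- list(f = function(x, a) 0, g = function(x) 1, x0 = 0,
               do_da = function(mu_x, a) matrix(0), na = 1)
  out <- link_cycle(link, mod, proc, steps = 0, dt = 1 / 24)
  expect_equal(out$posterior_o, c(0.3, 0.7))
  # degenerate single-model link is certain
  l1 <- link_spec(models[1], 1)
  out1 <- link_cycle(l1, mod, proc, steps = 24, dt = 1 / 24, seed = 1)
  expect_equal(out1$posterior_o, 1)
})

test_that("accumulated evidence identifies the generating outcome model", {
  models <- list(list(eta = -1, Pi = matrix(4)), list(eta = 1, Pi = matrix(4)))
  mod <- continuous_model(g = function(x, v) v, nx = 0, nv = 1, no = 1,
                          n_orders = 1, Pi_o = 8, eta = 0, Pi_eta = 1)
  hits <- 0L
  for (seed in 1:20) {
    k <- 1L + seed %% 2L
    link <- link_spec(models, c(0.5, 0.5))
    proc <- list(f = function(x, a) 0, g = function(x) models[[k]]$eta,
                 x0 = 0, do_da = function(mu_x, a) matrix(0), na = 1,
                 sd_o = sqrt(1 / 8))
    out <- link_cycle(link, mod, proc, steps = 24, dt = 1 / 24, seed = seed)
    hits <- hits + (which.max(out$posterior_o) == k)
  }
  expect_gte(hits, 18L)
})

test_that("longer evidence windows concentrate the posterior on the truth", {
  models <- list(list(eta = -1, Pi = matrix(4)), list(eta = 1, Pi = matrix(4)))
  mod <- continuous_model(g = function(x, v) v, nx = 0, nv = 1, no = 1,
                          n_orders = 1, Pi_o = 8, eta = 0, Pi_eta = 1)
  mass <- vapply(c(6L, 12L, 24L), function(steps) {
    mean(vapply(1:20, function(seed) {
      link <- link_spec(models, c(0.5, 0.5))
      proc <- list(f = function(x, a) 0, g = function(x) -1, x0 = 0,
                   do_da = function(mu_x, a) matrix(0), na = 1,
                   sd_o = sqrt(1 / 8))
      link_cycle(link, mod, proc, steps = steps, dt = 1 / 24,
                 seed = seed)$posterior_o[1]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mass) >= 0))
})
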
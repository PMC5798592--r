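# fixture builders shared across the suite (all generated in code)

# random small model: |S| <= 4, T <= 4, <= 3 policies, 3 outcomes, 2 actions
random_small_model <- function(n = sample(2:4, 1), T = sample(2:4, 1),
                               n_pol = sample(1:3, 1), n_out = 3L) {
  A <- normalize_columns(matrix(stats::runif(n_out * n), n_out, n))
  B <- array(0, c(n, n, 2L))
  for (a in 1:2) B[, , a] <- normalize_columns(matrix(stats::runif(n * n), n, n))
  pol <- array(sample(1:2, (T - 1L) * n_pol, TRUE), c(T - 1L, n_pol, 1L))
  discrete_model(A = A, B = B, D = norm_vec(stats::runif(n)),
                 policies = pol, control = 1L, T = T)
}

norm_vec <- function(x) x / sum(x)

# uniform-transition model with random likelihood and prior
uniform_B_model <- function(n = sample(2:5, 1), T = sample(2:4, 1),
                            n_out = sample(2:4, 1)) {
  discrete_model(
    A = normalize_columns(matrix(stats::runif(n_out * n) + 0.05, n_out, n)),
    B = array(1 / n, c(n, n, 1L)),
    D = norm_vec(stats::runif(n) + 0.05),
    T = T
  )
}

# deterministic model: cyclic permutation transitions, identity likelihood
permutation_model <- function(n = 3L, T = 4L) {
  P <- diag(n)[, c(2:n, 1L)]
  discrete_model(A = diag(n), B = array(P, c(n, n, 1L)),
                 D = one_hot_vec(1L, n), T = T)
}

one_hot_vec <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

# random observation list: each epoch observed with probability p_obs
random_observations <- function(model, p_obs = 0.6) {
  lapply(seq_len(model$T), function(t) {
    if (stats::runif(1) < p_obs) sample(seq_len(model$n_out[1L]), 1L) else NULL
  })
}

# simple static 1-D continuous model: o = v + noise, conjugate Gaussian
static_cause_model <- function(pi_o = 4, pi_eta = 2, eta = 0.3) {
  continuous_model(g = function(x, v) v, nx = 0L, nv = 1L, no = 1L,
                   n_orders = 1L, Pi_o = pi_o, eta = eta, Pi_eta = pi_eta)
}

# random Gaussian-linear BMR instance in d dimensions; returns the analytic
# posterior under the full prior plus everything the oracle needs
random_bmr_instance <- function(d = 1L) {
  eta_f <- stats::rnorm(d)
  Pi_f <- crossprod(matrix(stats::rnorm(d * d), d)) + diag(0.5, d)
  eta_r <- eta_f + stats::rnorm(d)
  Pi_r <- crossprod(matrix(stats::rnorm(d * d), d)) + diag(0.5, d)
  G <- diag(stats::runif(d, 0.5, 1.5), d)        # observation map
  Pi_l <- diag(stats::runif(d, 0.5, 2), d)       # likelihood precision
  o <- stats::rnorm(d, 0, 1.5)
  P_post <- Pi_f + crossprod(G, Pi_l %*% G)
  mu_post <- solve(P_post, Pi_f %*% eta_f + crossprod(G, Pi_l %*% o))
  loglik <- function(v) {
    if (is.matrix(v)) {
      dv <- sweep(v %*% t(G), 2L, o)
      -0.5 * rowSums((dv %*% Pi_l) * dv) - 0.5 * d * log(2 * pi) +
        0.5 * determinant(Pi_l, logarithm = TRUE)$modulus[1L]
    } else {
      dv <- as.numeric(G %*% v) - o
      -0.5 * sum(dv * (Pi_l %*% dv)) - 0.5 * d * log(2 * pi) +
        0.5 * determinant(Pi_l, logarithm = TRUE)$modulus[1L]
    }
  }
  list(
    full = list(mean = eta_f, precision = Pi_f),
    reduced = list(mean = eta_r, precision = Pi_r),
    posterior = list(mean = as.numeric(mu_post), precision = P_post),
    loglik = loglik
  )
}
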
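#' Exact posterior by enumeration of state sequences
#'
#' Brute-force reference computation for testing the engine: sums the joint
#' `P(o, s_{1:T} | policy)` over every state sequence (in linear space) and
#' returns the exact smoothed per-epoch marginals, the joint over sequences,
#' and the log evidence of the observation sequence. Intended for tiny
#' instances only; refuses when the sequence count exceeds `max_sequences`.
#'
#' @param model A [discrete_model()].
#' @param observations List over epochs of outcome indices (or lists per
#'   modality); `NULL` entries are unobserved.
#' @param policy Policy index.
#' @param max_sequences Enumeration cap (default 1e6).
#' @param D_override Optional per-factor initial-prior replacement.
#' @return List with `marginals` (`n_joint x T` matrix), `joint` (vector of
#'   sequence probabilities), `sequences` (matrix of state indices) and
#'   `log_evidence`.
#' @export
enumerate_posterior <- function(model, observations, policy = 1L,
                                max_sequences = 1e6, D_override = NULL) {
  T <- model$T
  n <- model$n_joint
  if (n^T > max_sequences) stopf("enumerate_posterior: %g sequences exceeds cap", n^T)

  d <- joint_D(model, D_override)
  Bs <- if (T > 1L) lapply(seq_len(T - 1L), function(t)
    normalize_columns(joint_B(model, policy, t))) else list()
  A <- lapply(model$A, normalize_columns)

  lik <- matrix(1, n, T)
  for (tau in seq_len(min(T, length(observations)))) {
    obs <- observations[[tau]]
    if (is.null(obs)) next
    if (!is.list(obs)) obs <- list(obs)
    for (m in seq_along(obs)) {
      o <- obs[[m]]
      if (is.null(o)) next
      if (length(o) == 1L) {
        lik[, tau] <- lik[, tau] * A[[m]][o, ]
      } else {
        # soft evidence: expected likelihood under the outcome distribution
        lik[, tau] <- lik[, tau] * as.vector(o %*% A[[m]])
      }
    }
  }

  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), T)))
  joint <- apply(seqs, 1L, function(sq) {
    p <- d[sq[1L]] * lik[sq[1L], 1L]
    if (T > 1L) for (t in 2:T) p <- p * Bs[[t - 1L]][sq[t], sq[t - 1L]] * lik[sq[t], t]
    p
  })
  Z <- sum(joint)
  post <- joint / Z
  marg <- matrix(0, n, T)
  for (t in seq_len(T)) {
    marg[, t] <- vapply(seq_len(n), function(s) sum(post[seqs[, t] == s]), numeric(1))
  }
  list(marginals = marg, joint = post, sequences = seqs, log_evidence = log(Z))
}

#' Exact expected free energy by explicit summation
#'
#' Independent reference for [expected_free_energy()]: loops explicitly over
#' outcomes and states, computing risk as the divergence of predicted from
#' preferred outcomes and ambiguity as the expected conditional outcome
#' entropy, without reusing the engine's vectorized path.
#'
#' @inheritParams expected_free_energy
#' @return Expected free energy (nats, scalar).
#' @export
enumerate_G <- function(model, s, tau = seq_len(model$T)) {
  A <- lapply(model$A, normalize_columns)
  G <- 0
  for (t in tau) {
    st <- s[, t]
    for (m in seq_along(A)) {
      a <- A[[m]]
      for (i in seq_len(nrow(a))) {
        o_i <- 0
        for (j in seq_len(ncol(a))) o_i <- o_i + a[i, j] * st[j]
        G <- G + o_i * (ln_safe(o_i) - model$C[[m]][i, t])
      }
      # ambiguity: expected conditional entropy of this modality
      for (j in seq_len(ncol(a))) {
        h_j <- 0
        for (i in seq_len(nrow(a))) h_j <- h_j - a[i, j] * ln_safe(a[i, j])
        G <- G + st[j] * h_j
      }
    }
  }
  G
}

#' Gaussian model evidence by numerical quadrature
#'
#' Numerically integrates an unnormalized posterior `prior x likelihood`
#' over one or two dimensions, returning the log evidence. Used as the
#' oracle for the link node's reduced (post hoc) Bayesian model comparison.
#' The grid adapts in two stages: a coarse scan locates the integrand's
#' mode and spread, then a fine rule (adaptive `stats::integrate` in 1-D, a
#' tensor-product Simpson grid in 2-D) integrates around it.
#'
#' @param prior_mean,prior_cov Gaussian prior moments (scalar/vector and
#'   scalar/matrix).
#' @param loglik Function returning the log likelihood of the (fixed) data
#'   at a latent value. It may be vectorized: in 1-D over a numeric vector,
#'   in 2-D over the rows of an `n x 2` matrix (a scalar-only function is
#'   detected and wrapped automatically).
#' @param half_width Coarse-scan half-width in prior standard deviations
#'   (default 16).
#' @param n_grid Number of Simpson nodes per dimension for the fine 2-D
#'   grid (odd; default 801).
#' @return Log evidence (scalar).
#' @export
gaussian_evidence_quadrature <- function(prior_mean, prior_cov, loglik,
                                         half_width = 16, n_grid = 801L) {
  d <- length(prior_mean)
  if (d > 2L) stopf("gaussian_evidence_quadrature: dimension must be <= 2")
  prior_cov <- as.matrix(prior_cov)
  sds <- sqrt(diag(prior_cov))
  if (!is.finite(loglik(if (d == 1L) prior_mean else rbind(prior_mean))[1L])) {
    stopf("gaussian_evidence_quadrature: non-finite integrand")
  }

  if (d == 1L) {
    ll <- function(v) {
      out <- tryCatch(loglik(v), error = function(e) NULL)
      if (is.null(out) || length(out) != length(v)) {
        out <- vapply(v, loglik, numeric(1))
      }
      out
    }
    # coarse scan for the mode and spread of the integrand
    grid <- seq(prior_mean - half_width * sds, prior_mean + half_width * sds,
                length.out = 4001L)
    lg <- ll(grid) + stats::dnorm(grid, prior_mean, sds, log = TRUE)
    shift <- max(lg)
    wts <- exp(lg - shift)
    mode <- grid[which.max(lg)]
    spread <- max(sqrt(sum(wts * (grid - mode)^2) / sum(wts)), diff(grid[1:2]))
    f <- function(v) exp(ll(v) - shift) * stats::dnorm(v, prior_mean, sds)
    val <- stats::integrate(f, mode - 14 * spread, mode + 14 * spread,
                            rel.tol = 1e-11, abs.tol = 0,
                            subdivisions = 800L)$value
    return(log(val) + shift)
  }

  ll2 <- function(pts) {
    out <- tryCatch(loglik(pts), error = function(e) NULL)
    if (is.null(out) || length(out) != nrow(pts)) {
      out <- apply(pts, 1L, loglik)
    }
    out
  }
  P <- solve(prior_cov)
  logdet <- determinant(prior_cov, logarithm = TRUE)$modulus[1L]
  log_prior <- function(pts) {
    dv <- sweep(pts, 2L, prior_mean)
    -0.5 * rowSums((dv %*% P) * dv) - 0.5 * logdet - log(2 * pi)
  }
  # stage 1: coarse scan
  cg <- lapply(1:2, function(i) seq(prior_mean[i] - half_width * sds[i],
                                    prior_mean[i] + half_width * sds[i],
                                    length.out = 161L))
  pts <- as.matrix(expand.grid(cg[[1L]], cg[[2L]]))
  lg <- ll2(pts) + log_prior(pts)
  shift <- max(lg)
  wts <- exp(lg - shift)
  mode <- pts[which.max(lg), ]
  spread <- vapply(1:2, function(i) {
    max(sqrt(sum(wts * (pts[, i] - mode[i])^2) / sum(wts)),
        diff(cg[[i]][1:2]))
  }, numeric(1))
  # stage 2: fine Simpson grid around the mode
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L
  fg <- lapply(1:2, function(i) seq(mode[i] - 10 * spread[i],
                                    mode[i] + 10 * spread[i],
                                    length.out = n_grid))
  w <- c(1, rep(c(4, 2), length.out = n_grid - 2L), 1)
  pts <- as.matrix(expand.grid(fg[[1L]], fg[[2L]]))
  vals <- matrix(exp(ll2(pts) + log_prior(pts) - shift), n_grid, n_grid)
  h1 <- diff(fg[[1L]][1:2]); h2 <- diff(fg[[2L]][1:2])
  val <- (h1 / 3) * (h2 / 3) * as.numeric(t(w) %*% vals %*% w)
  log(val) + shift
}
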
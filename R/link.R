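#' Specify a discrete-continuous link factor
#'
#' The link node treats each discrete outcome as a model of continuous
#' dynamics, defined by a Gaussian prior over the hidden causes `v` of a
#' continuous level. Descending messages convert a categorical prior over
#' outcomes into a single (moment-matched) Gaussian empirical prior;
#' ascending messages convert accumulated continuous evidence back into a
#' categorical posterior via post hoc (reduced) Bayesian model comparison.
#'
#' @param models List of outcome models, each a list with `eta` (prior mean
#'   over causes) and `Pi` (prior precision, SPD).
#' @param prior_o Descending categorical prior over the outcome models.
#' @return Object of class `link_spec` with accumulated relative log
#'   evidences `L` (zero at accumulation time 0), free energies `E` and
#'   `posterior_o`.
#' @export
link_spec <- function(models, prior_o = NULL) {
  n <- length(models)
  prior_o <- prior_o %||% rep(1 / n, n)
  if (abs(sum(prior_o) - 1) > 1e-8) stopf("link_spec: prior_o must be normalized")
  structure(list(
    models = models,
    prior_o = as.numeric(prior_o),
    L = numeric(n),
    E = -ln_safe(prior_o),
    posterior_o = as.numeric(prior_o),
    T_accum = 0
  ), class = "link_spec")
}

#' @export
print.link_spec <- function(x, ...) {
  cat(sprintf("<link_spec: %d outcome model(s), accumulated T = %.4g>\n",
              length(x$models), x$T_accum))
  invisible(x)
}

#' Descending Gaussian prior over hidden causes
#'
#' Prior expectations about hidden causes are averaged over outcome models:
#' the categorical mixture of Gaussian priors is moment-matched to a single
#' Gaussian (mean `sum_m o_m eta_m`; covariance the mixture covariance),
#' which is what the continuous level consumes as `(eta, Pi_eta)`.
#'
#' @param models List of outcome models (`eta`, `Pi`).
#' @param prior_o Normalized categorical prior over the models.
#' @return List with `mean` and `precision` (class `gaussian_belief`).
#' @export
descending_prior <- function(models, prior_o) {
  stopifnot(abs(sum(prior_o) - 1) < 1e-8)
  d <- length(models[[1L]]$eta)
  mu <- numeric(d)
  for (m in seq_along(models)) mu <- mu + prior_o[m] * models[[m]]$eta
  S <- matrix(0, d, d)
  for (m in seq_along(models)) {
    Sm <- solve(models[[m]]$Pi)
    dm <- models[[m]]$eta - mu
    S <- S + prior_o[m] * (Sm + tcrossprod(dm))
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stopf("descending_prior: mixture covariance not positive definite")
  structure(list(mean = mu, precision = solve(S)), class = "gaussian_belief")
}

#' Reduced (post hoc) log evidence of an alternative prior
#'
#' Scores a reduced prior `(eta_m, Pi_m)` against the posterior obtained
#' under the full prior, without refitting: the Gaussian reduced-evidence
#' identity in the four precisions involved,
#' `ln P(o | eta_m) - ln P(o | eta)`.
#'
#' @param posterior,full,reduced Gaussian beliefs: lists with `mean` and
#'   `precision` (SPD).
#' @return Relative log evidence `L_m` (nats).
#' @export
reduced_log_evidence <- function(posterior, full, reduced) {
  P <- as.matrix(posterior$precision)
  Pf <- as.matrix(full$precision)
  Pr <- as.matrix(reduced$precision)
  Pc <- P + Pr - Pf
  ev <- eigen(Pc, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stopf("reduced_log_evidence: reduced posterior precision not SPD (ill-posed reduction)")
  b <- P %*% posterior$mean + Pr %*% reduced$mean - Pf %*% full$mean
  mu_c <- solve(Pc, b)
  ld <- function(M) determinant(as.matrix(M), logarithm = TRUE)$modulus[1L]
  0.5 * (ld(Pr) - ld(Pf) + ld(P) - ld(Pc)) +
    0.5 * (sum(b * mu_c) -
           sum(posterior$mean * (P %*% posterior$mean)) -
           sum(reduced$mean * (Pr %*% reduced$mean)) +
           sum(full$mean * (Pf %*% full$mean)))
}

#' Accumulate continuous evidence over a window
#'
#' Riemann-sums the instantaneous relative log evidence of every outcome
#' model over posterior snapshots from the continuous engine:
#' `L_m <- L_m + sum_steps L_m(t) dt`, then
#' `E_m = -ln prior_o_m - L_m` and `posterior_o = softmax(-E)`. With an
#' empty window the ascending posterior reduces to the descending prior.
#'
#' @param link A [link_spec()].
#' @param snapshots List of posterior snapshots, each a list with `mean`
#'   and `precision` over the hidden causes (see [link_cycle()]).
#' @param dt Time per snapshot.
#' @param full The full (descending, moment-matched) prior used by the
#'   continuous level; defaults to `descending_prior(link$models,
#'   link$prior_o)`.
#' @return The updated [link_spec()].
#' @export
accumulate_evidence <- function(link, snapshots, dt, full = NULL) {
  full <- full %||% descending_prior(link$models, link$prior_o)
  for (snap in snapshots) {
    L_t <- vapply(link$models, function(m) {
      reduced_log_evidence(snap, full, list(mean = m$eta, precision = m$Pi))
    }, numeric(1))
    link$L <- link$L + L_t * dt
    link$T_accum <- link$T_accum + dt
  }
  link$E <- -ln_safe(link$prior_o) - link$L
  link$posterior_o <- softmax(-link$E)
  link
}

#' Run one full link-node cycle
#'
#' Installs the descending Bayesian-model-average prior in the continuous
#' model, co-integrates the filter and process over the window, accumulates
#' reduced-evidence snapshots at every integration step, and returns the
#' ascending categorical posterior over outcome models together with the
#' continuous trajectory.
#'
#' @param link A [link_spec()].
#' @param model A [continuous_model()] whose causes match the link models.
#' @param process Continuous process (see [integrate_active()]).
#' @param steps,dt Window length and integration step.
#' @param stream RNG substream (or `seed`).
#' @param seed Seed when no stream is given.
#' @param state Optional initial [generalized_state()].
#' @param gain Action gain.
#' @param substeps Euler micro-steps per integration step (see
#'   [filter_step()]).
#' @return List with `link` (updated), `posterior_o`, `trajectory` and
#'   `prior` (the installed Gaussian prior).
#' @export
link_cycle <- function(link, model, process, steps, dt, stream = NULL,
                       seed = 1L, state = NULL, gain = 1, substeps = 1L) {
  d <- length(link$models[[1L]]$eta)
  if (d != model$nv) stopf("link_cycle: cause dimensionality mismatch")
  prior <- descending_prior(link$models, link$prior_o)
  model$eta <- prior$mean
  model$Pi_eta <- prior$precision

  snapshot <- function(mod, st, obs) {
    J <- model_jacobians(mod, if (mod$nx) st$mu_x[, 1L] else numeric(0), st$mu_v)
    list(mean = st$mu_v,
         precision = mod$Pi_eta + crossprod(J$gv, mod$Pi_o[[1L]] %*% J$gv))
  }
  traj <- NULL
  if (steps > 0L) {
    traj <- integrate_active(model, process, steps = steps, dt = dt,
                             stream = stream, seed = seed, state = state,
                             gain = gain, snapshot = snapshot,
                             substeps = substeps)
    link <- accumulate_evidence(link, traj$snapshots, dt, full = prior)
  } else {
    link$E <- -ln_safe(link$prior_o)
    link$posterior_o <- link$prior_o
  }
  list(link = link, posterior_o = link$posterior_o, trajectory = traj,
       prior = prior)
}
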
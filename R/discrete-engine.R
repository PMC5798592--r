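#' Likelihood message from observed outcomes
#'
#' The log-space message sent from the likelihood factor to the hidden-state
#' edge: `ln(A . o)` summed over modalities, where `A . o` applies the
#' transpose-normalized likelihood (rows of `A` normalized, then transposed)
#' to the observed outcome. Outcomes may be hard (an index) or soft (a
#' probability vector, as delivered by an ascending message or a link node).
#' Unobserved modalities or epochs contribute a zero vector.
#'
#' @param A Likelihood matrix over joint states, or list per modality.
#' @param obs Outcome observation(s): an integer index, a probability vector,
#'   `NULL` (unobserved), or a list of these (one per modality).
#' @return Log-space vector (nats) over joint hidden states.
#' @export
likelihood_message <- function(A, obs) {
  if (!is.list(A)) A <- list(A)
  if (!is.list(obs)) obs <- list(obs)
  n <- ncol(A[[1L]])
  msg <- numeric(n)
  for (m in seq_along(A)) {
    o <- if (m <= length(obs)) obs[[m]] else NULL
    if (is.null(o)) next
    if (length(o) == 1L) {
      if (o < 1L || o > nrow(A[[m]])) stopf("likelihood_message: outcome index out of range")
      o <- one_hot(o, nrow(A[[m]]))
    }
    msg <- msg + ln_safe(bt_normalize(A[[m]]) %*% o)[, 1L]
  }
  msg
}

#' Forward message through a transition factor
#'
#' `ln(B s)` with `B` column-stochastic: the empirical prior passed from the
#' previous epoch's expectations to the current epoch.
#'
#' @param B Transition matrix (columns: previous state).
#' @param s Expectation vector at the previous epoch.
#' @return Log-space vector over states at the current epoch.
#' @export
forward_message <- function(B, s) {
  ln_safe(normalize_columns(B) %*% s)[, 1L]
}

#' Backward message through a transition factor
#'
#' `ln(B . s)` where the dot denotes the separately normalized transpose
#' (`B[i,j] -> B[j,i] / sum_k B[j,k]`): the empirical prior passed back from
#' the subsequent epoch's expectations.
#'
#' @param B Transition matrix governing the step from the current epoch to
#'   the next.
#' @param s Expectation vector at the subsequent epoch.
#' @return Log-space vector over states at the current epoch.
#' @export
backward_message <- function(B, s) {
  ln_safe(bt_normalize(B) %*% s)[, 1L]
}

# all incoming messages for one policy: list of T log-space vectors
collect_messages <- function(model, observations, policy, s, D_override = NULL) {
  T <- model$T
  msgs <- vector("list", T)
  d <- ln_safe(joint_D(model, D_override))
  for (tau in seq_len(T)) {
    m <- if (tau == 1L) d else
      forward_message(joint_B(model, policy, tau - 1L), s[, tau - 1L])
    if (tau < T) m <- m + backward_message(joint_B(model, policy, tau), s[, tau + 1L])
    obs <- if (tau <= length(observations)) observations[[tau]] else NULL
    if (!is.null(obs)) m <- m + likelihood_message(model$A, obs)
    msgs[[tau]] <- m
  }
  msgs
}

#' Posterior expectations over hidden states (fixed-point scheme)
#'
#' Iterates the belief-propagation fixed point
#' `s_tau <- softmax(forward + backward + likelihood)` over all epochs (past
#' and future are represented at all times) until the largest elementwise
#' change falls below `tol`. Observations may cover any subset of epochs;
#' unobserved epochs contribute no likelihood message.
#'
#' @param model A [discrete_model()].
#' @param observations List over epochs; each element an outcome index,
#'   probability vector, list per modality, or `NULL` for unobserved epochs.
#' @param policy Policy index (default 1).
#' @param tol Convergence tolerance on expectations (default 1e-6).
#' @param max_sweeps Maximum number of sweeps (default 64).
#' @param D_override Optional list of per-factor initial priors replacing `D`
#'   (used for descending empirical priors in deep models).
#' @return Matrix `n_joint x T` of posterior expectations, with attribute
#'   `"converged"`.
#' @export
state_update_fixed_point <- function(model, observations, policy = 1L,
                                     tol = 1e-6, max_sweeps = 64L,
                                     D_override = NULL) {
  T <- model$T
  n <- model$n_joint
  s <- matrix(1 / n, n, T)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    msgs <- collect_messages(model, observations, policy, s, D_override)
    for (tau in seq_len(T)) {
      s_new <- softmax(msgs[[tau]])
      delta <- max(delta, max(abs(s_new - s[, tau])))
      s[, tau] <- s_new
      if (tau < T) {
        # refresh downstream messages with the updated expectation
        msgs <- collect_messages(model, observations, policy, s, D_override)
      }
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warnf("state_update_fixed_point: no convergence after %d sweeps (last delta above tol)",
          max_sweeps)
  }
  attr(s, "converged") <- converged
  s
}

#' Posterior expectations by gradient flow on free energy
#'
#' The process-theory update: a state prediction error
#' `eps = (forward + backward + likelihood) - ln s` drives the depolarization
#' `nu <- nu + step * eps`, with firing rates `s = softmax(nu)`. Two message
#' conventions are provided, differing only in the temporal (empirical
#' prior) messages:
#'
#' * `"sum_product"` (default): the log of the expected transition,
#'   `ln(B s)`, matching the forward/backward matrix multiplications of the
#'   fixed-point scheme. This is the convention used by the simulations
#'   (it preserves ties between equally plausible narratives). Its recorded
#'   `F` - the self-consistent marginal free energy
#'   `sum_tau s_tau . (ln s_tau - messages_tau)` - is stationary at the
#'   fixed point but is not an exact Lyapunov function: the message field is
#'   not conservative, so `F` can rise transiently.
#' * `"variational"`: the mean-field messages (the expectation of the log
#'   transition, `(ln B) s`), for which `eps` is exactly the negative
#'   gradient of the mean-field variational free energy; `F` then never
#'   increases along iterations (prediction errors are destroyed as the
#'   descent reaches its attracting point).
#'
#' The two conventions coincide for uniform transitions and for hard
#' observations under deterministic models, where both equal the exact
#' posterior. At a stationary point the error has equal components (softmax
#' gauge).
#'
#' @inheritParams state_update_fixed_point
#' @param iterations Number of gradient iterations (default 16, the count
#'   used per epoch in the reading simulations).
#' @param step Step size on the depolarization (default 0.25).
#' @param init Optional initial expectations (`n_joint x T` matrix).
#' @param messages Temporal message convention (see Details).
#' @param record_trace If `TRUE`, also return the per-iteration expectations
#'   (used for simulated rasters).
#' @return A list with elements `s` (expectations), `nu` (depolarizations),
#'   `eps` (final state prediction errors), `F_trace` (free energy per
#'   iteration, nats) and optionally `s_trace` (list of per-iteration
#'   expectation matrices).
#' @export
state_update_gradient <- function(model, observations, policy = 1L,
                                  iterations = 16L, step = 0.25,
                                  init = NULL, D_override = NULL,
                                  messages = c("sum_product", "variational"),
                                  record_trace = FALSE) {
  messages <- match.arg(messages)
  T <- model$T
  n <- model$n_joint
  s <- init %||% matrix(1 / n, n, T)
  nu <- ln_safe(s)

  lnD <- ln_safe(joint_D(model, D_override))
  Bj <- if (T > 1L) lapply(seq_len(T - 1L), function(t)
    normalize_columns(joint_B(model, policy, t))) else list()
  lnB <- lapply(Bj, ln_safe)
  lik <- matrix(0, n, T)
  for (tau in seq_len(min(T, length(observations)))) {
    if (!is.null(observations[[tau]])) {
      lik[, tau] <- likelihood_message(model$A, observations[[tau]])
    }
  }

  collect <- function(s) {
    M <- lik
    M[, 1L] <- M[, 1L] + lnD
    if (T > 1L) for (t in seq_len(T - 1L)) {
      if (messages == "variational") {
        M[, t + 1L] <- M[, t + 1L] + lnB[[t]] %*% s[, t]
        M[, t] <- M[, t] + crossprod(lnB[[t]], s[, t + 1L])
      } else {
        M[, t + 1L] <- M[, t + 1L] + ln_safe(Bj[[t]] %*% s[, t])
        M[, t] <- M[, t] + ln_safe(bt_normalize(Bj[[t]]) %*% s[, t + 1L])
      }
    }
    M
  }
  free_energy <- function(s, M) {
    if (messages == "variational") {
      Fv <- sum(s * ln_safe(s)) - sum(s[, 1L] * lnD) - sum(s * lik)
      if (T > 1L) for (t in seq_len(T - 1L)) {
        Fv <- Fv - sum(s[, t + 1L] * (lnB[[t]] %*% s[, t]))
      }
      Fv
    } else {
      sum(s * (ln_safe(s) - M))
    }
  }

  F_trace <- numeric(iterations)
  s_trace <- if (record_trace) vector("list", iterations) else NULL
  eps <- matrix(0, n, T)
  for (it in seq_len(iterations)) {
    M <- collect(s)
    eps <- M - ln_safe(s)
    nu <- nu + step * eps
    s <- apply(nu, 2L, softmax)
    F_trace[it] <- free_energy(s, collect(s))
    if (record_trace) s_trace[[it]] <- s
  }
  if (messages == "variational" && iterations > 2L &&
      any(diff(F_trace) > 1e-9)) {
    warnf("state_update_gradient: free energy increased beyond jitter (divergence)")
  }
  out <- list(s = s, nu = nu, eps = eps, F_trace = F_trace)
  if (record_trace) out$s_trace <- s_trace
  out
}

#' Predicted outcomes under expected states
#'
#' `o = A s` per modality (with `A` column-normalized): the outcomes expected
#' under a policy's state expectations, used to evaluate expected free energy.
#'
#' @param A Likelihood matrix or list per modality.
#' @param s Expectation vector over joint states (or `n x T` matrix).
#' @return List per modality of predicted outcome vectors (or matrices).
#' @export
expected_outcomes <- function(A, s) {
  if (!is.list(A)) A <- list(A)
  lapply(A, function(a) {
    o <- normalize_columns(a) %*% s
    if (is.matrix(s)) o else o[, 1L]
  })
}

#' Expected free energy of a policy
#'
#' `G(pi) = sum_tau [ o_tau . (ln o_tau - C_tau) + s_tau . H ]` over the
#' requested epochs: the risk (relative entropy between predicted and
#' preferred outcomes, via the outcome prediction error `ln o - C`) plus the
#' ambiguity expected under the states.
#'
#' @param model A [discrete_model()].
#' @param s Matrix `n_joint x T` of policy-conditioned expectations.
#' @param tau Integer vector of epochs to include (default all); in an
#'   action-perception cycle at time `t` only future epochs `tau > t`
#'   contribute.
#' @return Expected free energy (nats, scalar).
#' @export
expected_free_energy <- function(model, s, tau = seq_len(model$T)) {
  G <- 0
  for (t in tau) {
    st <- s[, t]
    o <- expected_outcomes(model$A, st)
    for (m in seq_along(o)) {
      G <- G + sum(o[[m]] * (ln_safe(o[[m]]) - model$C[[m]][, t]))
    }
    G <- G + sum(st * model$H)
  }
  G
}

#' Posterior over policies
#'
#' `pi = softmax(-gamma * G)`: policies are more probable a priori when they
#' minimize expected free energy.
#'
#' @param G Vector of expected free energies (nats).
#' @param gamma Precision of policy selection (default 1).
#' @return Probability vector over policies.
#' @export
policy_posterior <- function(G, gamma = 1) {
  if (any(!is.finite(G))) stopf("policy_posterior: non-finite expected free energy")
  softmax(-gamma * G)
}

#' Bayesian model average of state expectations over policies
#'
#' `bma_tau = sum_pi pi(pi) s_(pi,tau)`.
#'
#' @param s_by_policy List (one per policy) of expectation vectors or
#'   `n x T` matrices.
#' @param pi Posterior over policies.
#' @return Averaged expectations with the same shape as each element.
#' @export
bayesian_model_average <- function(s_by_policy, pi) {
  out <- Reduce(`+`, Map(function(s, w) w * s, s_by_policy, as.list(pi)))
  if (is.matrix(out)) {
    sweep(out, 2L, colSums(out), "/")
  } else {
    norm_vec(out)
  }
}

#' Select the most probable action
#'
#' Marginalizes the policy posterior onto actions at time `t`
#' (`u(a) = sum over policies prescribing a`) and returns the argmax per
#' controlled factor; ties are broken toward the lowest action index.
#'
#' @param pi Posterior over policies.
#' @param policies Policy array `(transitions x policies x controlled factors)`.
#' @param t Transition index (action taken between epochs `t` and `t + 1`).
#' @return Integer vector of selected action indices (one per controlled
#'   factor); zero-length when nothing is controlled.
#' @export
select_action <- function(pi, policies, t) {
  n_ctrl <- dim(policies)[3L]
  if (n_ctrl == 0L) return(integer(0))
  vapply(seq_len(n_ctrl), function(j) {
    acts <- policies[t, , j]
    u <- tapply(pi, acts, sum)
    cand <- as.integer(names(u))
    cand[which.max(u)]  # which.max keeps the first (lowest) index on ties
  }, integer(1))
}

#' Advance the generative process by one action
#'
#' Samples the next true states from the process's transition arrays given
#' the action, then samples an outcome from the process's likelihood. The
#' generative process is distinct from the generative model: it consumes a
#' named RNG substream so model-side computation stays seed-independent.
#'
#' @param states Integer vector of current true states (one per factor).
#' @param action Integer vector of actions for the controlled factors
#'   (in the order of `process$control`).
#' @param process A [discrete_model()] describing the true environment.
#' @param stream An [rng_stream()] for process sampling.
#' @return List with `states` (next true states) and `outcome` (sampled
#'   outcome index per modality).
#' @export
step_process <- function(states, action, process, stream) {
  next_states <- integer(process$n_factors)
  for (f in seq_len(process$n_factors)) {
    a <- 1L
    j <- match(f, process$control)
    if (!is.na(j)) a <- action[j]
    p <- process$B[[f]][, states[f], a]
    next_states[f] <- with_stream(stream, sample_cat(p))
  }
  outcome <- sample_outcome(process, next_states, stream)
  list(states = next_states, outcome = outcome)
}

sample_outcome <- function(process, states, stream) {
  idx <- joint_index(states, process$n_states)
  vapply(process$A, function(a) with_stream(stream, sample_cat(a[, idx])), integer(1))
}

#' Run one trial of the action-perception cycle
#'
#' Per epoch: observe an outcome, update policy-conditioned state
#' expectations (gradient scheme, 16 iterations per epoch by default),
#' evaluate expected free energy over the remaining epochs, form the policy
#' posterior and its Bayesian model average, select and emit an action, and
#' step the generative process.
#'
#' @param model Generative model (a [discrete_model()]).
#' @param process Generative process (a [discrete_model()]; may equal the
#'   model). Ignored when `observe_fn` is supplied and `init_states` is given.
#' @param T Number of epochs (defaults to the model horizon).
#' @param scheme `"gradient"` (default) or `"fixed_point"` state updates.
#' @param iterations,step Gradient-scheme parameters.
#' @param gamma Policy precision.
#' @param seed Seed for the process substream (ignored when `stream` given).
#' @param stream Optional [rng_stream()] shared with an outer simulation.
#' @param D_override Optional per-factor initial-prior replacement (list with
#'   `NULL` for untouched factors), e.g. a descending empirical prior.
#' @param observe_fn Optional observation hook
#'   `function(t, predicted, true_states, stream)` returning a list per
#'   modality of outcome indices or soft probability vectors (used by the
#'   link node); defaults to sampling from the process likelihood.
#' @param init_states Optional true initial states (sampled from the process
#'   `D` otherwise).
#' @param record_iterations Keep per-iteration expectations for simulated
#'   electrophysiology.
#' @return A `bp_trial` object; see [tidy.bp_trial()] and
#'   [glance.bp_trial()].
#' @export
run_trial <- function(model, process = model, T = model$T,
                      scheme = c("gradient", "fixed_point"),
                      iterations = 16L, step = 0.25, gamma = 1,
                      seed = 1L, stream = NULL, D_override = NULL,
                      observe_fn = NULL, init_states = NULL,
                      record_iterations = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(T <= model$T)
  if (is.null(stream)) stream <- rng_stream(seed)
  n_pol <- model$n_policies

  true_states <- matrix(NA_integer_, model$n_factors, T)
  ts <- init_states %||% vapply(process$D, function(d)
    with_stream(stream, sample_cat(as.matrix(d)[, 1L])), integer(1))
  true_states[, 1L] <- ts

  observations <- vector("list", model$T)
  outcomes <- vector("list", T)
  actions <- if (T > 1L) matrix(NA_integer_, T - 1L, max(1L, length(model$control))) else
    matrix(NA_integer_, 0L, max(1L, length(model$control)))
  s_pol <- lapply(seq_len(n_pol), function(p) matrix(1 / model$n_joint, model$n_joint, model$T))
  pi_hist <- matrix(NA_real_, n_pol, T)
  G_hist <- matrix(NA_real_, n_pol, T)
  F_hist <- vector("list", T)
  bma_hist <- vector("list", T)
  iter_bma <- if (record_iterations) vector("list", T) else NULL
  extras <- vector("list", T)

  pi <- rep(1 / n_pol, n_pol)
  # policies inconsistent with actions already taken are precluded
  allowed <- rep(TRUE, n_pol)

  for (t in seq_len(T)) {
    # --- observe ---------------------------------------------------------
    pred <- expected_outcomes(model$A, bayesian_model_average(
      lapply(s_pol, function(s) s[, t]), pi))
    if (is.null(observe_fn)) {
      if (t == 1L) {
        obs <- as.list(sample_outcome(process, true_states[, t], stream))
      } else {
        obs <- as.list(outcomes[[t]])
      }
    } else {
      res <- observe_fn(t, pred, true_states[, t], stream)
      obs <- res$obs %||% res
      extras[[t]] <- res$extra
    }
    observations[[t]] <- obs
    outcomes[[t]] <- obs

    # --- update states per policy (in parallel, regardless of plausibility)
    traces <- vector("list", n_pol)
    for (p in seq_len(n_pol)) {
      if (scheme == "gradient") {
        up <- state_update_gradient(model, observations, p,
                                    iterations = iterations, step = step,
                                    init = s_pol[[p]], D_override = D_override,
                                    record_trace = record_iterations)
        s_pol[[p]] <- up$s
        traces[[p]] <- up
      } else {
        s_pol[[p]] <- state_update_fixed_point(model, observations, p,
                                               D_override = D_override)
        traces[[p]] <- list(F_trace = NA_real_)
      }
    }
    F_hist[[t]] <- vapply(traces, function(x) x$F_trace[length(x$F_trace)], numeric(1))

    # --- policy posterior and averages ------------------------------------
    future <- if (t < model$T) seq(t + 1L, model$T) else integer(0)
    if (length(future)) {
      G <- vapply(seq_len(n_pol), function(p)
        expected_free_energy(model, s_pol[[p]], future), numeric(1))
      pi <- policy_posterior(G, gamma)
      pi <- norm_vec(pi * allowed)
    } else {
      # no remaining choices: beliefs about the pursued policy persist
      G <- rep(0, n_pol)
    }
    G_hist[, t] <- G
    pi_hist[, t] <- pi
    bma_hist[[t]] <- bayesian_model_average(s_pol, pi)
    if (record_iterations) {
      iters <- length(traces[[1L]]$s_trace)
      iter_bma[[t]] <- lapply(seq_len(iters), function(it)
        bayesian_model_average(lapply(traces, function(x) x$s_trace[[it]]), pi))
    }

    # --- act and step the process -----------------------------------------
    if (t < T) {
      act <- select_action(pi, model$policies, t)
      if (length(act)) {
        actions[t, seq_along(act)] <- act
        for (j in seq_along(act)) {
          allowed <- allowed & (model$policies[t, , j] == act[j])
        }
        pi <- norm_vec(pi * allowed)
      }
      stepped <- step_process(true_states[, t], act, process, stream)
      true_states[, t + 1L] <- stepped$states
      outcomes[[t + 1L]] <- stepped$outcome
      if (!is.null(observe_fn)) outcomes[[t + 1L]] <- NULL
    }
  }

  structure(list(
    model = model, T = T,
    outcomes = observations[seq_len(T)],
    actions = actions, true_states = true_states,
    s_policies = s_pol, pi = pi_hist, G = G_hist, F = F_hist,
    bma = bma_hist, iter_bma = iter_bma, extras = extras,
    scheme = scheme
  ), class = "bp_trial")
}

#' @export
print.bp_trial <- function(x, ...) {
  cat(sprintf("<bp_trial: %d epoch(s), %d policy(ies), %d joint state(s)>\n",
              x$T, nrow(x$pi), x$model$n_joint))
  invisible(x)
}
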
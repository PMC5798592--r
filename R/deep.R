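#' Descending empirical prior from a higher level
#'
#' In a deep temporal model the initial-state factor of a lower level is
#' conditioned on the level above: `D` becomes a matrix whose columns are
#' indexed by the higher-level state (or predicted outcome). The descending
#' message is the matrix product with the higher level's Bayesian model
#' average, giving an empirical prior over the lower level's initial state.
#'
#' @param D Matrix `(lower states x higher categories)` with
#'   column-stochastic columns.
#' @param bma Higher-level Bayesian model average (probability vector over
#'   the higher categories).
#' @return Normalized prior over lower-level initial states.
#' @export
descending_message <- function(D, bma) {
  norm_vec((D %*% bma)[, 1L])
}

#' Ascending evidence from a lower level
#'
#' The lower level's posterior over its initial state is returned to the
#' level above as a log-evidence vector over the higher categories:
#' `evidence(l) = ln sum_j D[j, l] q(j)`, treated as an additional
#' likelihood term in the higher level's state update (it supplements the
#' observations of the level above).
#'
#' @param D Matrix `(lower states x higher categories)`.
#' @param q Lower-level posterior over its initial state.
#' @return Log-evidence vector (nats) over higher categories.
#' @export
ascending_message <- function(D, q) {
  ln_safe(crossprod(D, q))[, 1L]
}

#' Run a two-level deep temporal trial
#'
#' Implements the nested scheduling of deep temporal models: for each
#' higher-level epoch the higher level emits descending empirical priors
#' over the lower level's initial states, the full lower-level trial runs to
#' completion, ascending messages return the lower level's posterior as soft
#' outcomes for the higher level, and only then does the higher level update
#' (strict alternation; higher-level expectations wait until lower-level
#' updates have terminated).
#'
#' @param hi,lo Higher- and lower-level [discrete_model()]s.
#' @param interfaces List of interfaces, each a list with `modality` (higher
#'   outcome modality index), `factor` (lower state factor index) and `D`
#'   (matrix `lower states x higher outcomes` linking them).
#' @param hi_process Generative process for the higher level (defaults to
#'   `hi`). Non-interface modalities are observed directly from it.
#' @param lo_process_fn Function `(t, hi_true_states, stream)` returning the
#'   lower-level process for higher epoch `t` (defaults to `lo` itself).
#' @param lo_observe_fn Optional observation hook passed to the lower-level
#'   [run_trial()] (e.g. a link-node cycle).
#' @param ascending If `FALSE`, ascending messages are severed and the higher
#'   posterior equals its prior propagation (diagnostic).
#' @param seed Seed for the shared process substream.
#' @param iterations,step,gamma Engine parameters used at both levels.
#' @param record_iterations Keep per-iteration expectations at both levels.
#' @return A `bp_deep_trial` object containing the higher-level `bp_trial`
#'   fields plus `lower` (list of lower-level `bp_trial`s, one per higher
#'   epoch).
#' @export
run_deep <- function(hi, lo, interfaces, hi_process = hi,
                     lo_process_fn = NULL, lo_observe_fn = NULL,
                     ascending = TRUE, seed = 1L,
                     iterations = 16L, step = 0.25, gamma = 1,
                     record_iterations = FALSE) {
  for (itf in interfaces) {
    D <- itf$D
    if (nrow(D) != lo$n_states[itf$factor] || ncol(D) != hi$n_out[itf$modality]) {
      stopf("run_deep: interface dimensions do not match level interfaces (structural error)")
    }
  }
  stream <- rng_stream(seed)
  T <- hi$T
  n_pol <- hi$n_policies

  true_states <- matrix(NA_integer_, hi$n_factors, T)
  true_states[, 1L] <- vapply(hi_process$D, function(d)
    with_stream(stream, sample_cat(as.matrix(d)[, 1L])), integer(1))

  observations <- vector("list", T)
  s_pol <- lapply(seq_len(n_pol), function(p) matrix(1 / hi$n_joint, hi$n_joint, T))
  pi <- rep(1 / n_pol, n_pol)
  pi_hist <- matrix(NA_real_, n_pol, T)
  G_hist <- matrix(NA_real_, n_pol, T)
  bma_hist <- vector("list", T)
  iter_bma <- if (record_iterations) vector("list", T) else NULL
  lower <- vector("list", T)
  actions <- if (T > 1L) matrix(NA_integer_, T - 1L, max(1L, length(hi$control))) else
    matrix(NA_integer_, 0L, 1L)
  direct_outcome <- vector("list", T)
  direct_outcome[[1L]] <- sample_outcome(hi_process, true_states[, 1L], stream)

  interface_modalities <- vapply(interfaces, function(i) i$modality, integer(1))

  for (t in seq_len(T)) {
    # --- descending: predicted interface outcomes -> lower empirical priors
    bma_pred <- bayesian_model_average(lapply(s_pol, function(s) s[, t]), pi)
    pred <- expected_outcomes(hi$A, bma_pred)
    D_override <- vector("list", lo$n_factors)
    for (itf in interfaces) {
      D_override[[itf$factor]] <- descending_message(itf$D, pred[[itf$modality]])
    }

    # --- run the subordinate level to completion -------------------------
    lo_process <- if (is.null(lo_process_fn)) lo else
      lo_process_fn(t, true_states[, t], stream)
    lower[[t]] <- run_trial(lo, lo_process, stream = stream,
                            D_override = D_override,
                            observe_fn = lo_observe_fn,
                            iterations = iterations, step = step, gamma = gamma,
                            record_iterations = record_iterations)

    # --- ascending: lower posterior over initial states -> soft outcomes --
    obs <- vector("list", hi$n_modalities)
    for (m in seq_len(hi$n_modalities)) {
      if (m %in% interface_modalities) {
        if (ascending) {
          itf <- interfaces[[match(m, interface_modalities)]]
          q <- factor_marginal(lower[[t]]$bma[[lower[[t]]$T]][, 1L],
                               lo$n_states, itf$factor)
          obs[[m]] <- softmax(ascending_message(itf$D, q))
        } else {
          obs[[m]] <- NULL
        }
      } else {
        obs[[m]] <- direct_outcome[[t]][m]
      }
    }
    observations[[t]] <- obs

    # --- higher-level update (waits for the lower level) -----------------
    traces <- vector("list", n_pol)
    for (p in seq_len(n_pol)) {
      up <- state_update_gradient(hi, observations, p, iterations = iterations,
                                  step = step, init = s_pol[[p]],
                                  record_trace = record_iterations)
      s_pol[[p]] <- up$s
      traces[[p]] <- up
    }
    future <- if (t < T) seq(t + 1L, T) else integer(0)
    if (length(future)) {
      G <- vapply(seq_len(n_pol), function(p)
        expected_free_energy(hi, s_pol[[p]], future), numeric(1))
      pi <- policy_posterior(G, gamma)
    } else {
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

    if (t < T) {
      act <- select_action(pi, hi$policies, t)
      if (length(act)) actions[t, seq_along(act)] <- act
      stepped <- step_process(true_states[, t], act, hi_process, stream)
      true_states[, t + 1L] <- stepped$states
      direct_outcome[[t + 1L]] <- stepped$outcome
    }
  }

  structure(list(
    model = hi, T = T, outcomes = observations, actions = actions,
    true_states = true_states, s_policies = s_pol,
    pi = pi_hist, G = G_hist, bma = bma_hist, iter_bma = iter_bma,
    lower = lower, interfaces = interfaces
  ), class = c("bp_deep_trial", "bp_trial"))
}

#' @export
print.bp_deep_trial <- function(x, ...) {
  cat(sprintf("<bp_deep_trial: %d higher epoch(s), %d nested lower trial(s)>\n",
              x$T, length(x$lower)))
  invisible(x)
}
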
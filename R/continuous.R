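#' Specify a continuous (generalized-coordinate) state-space model
#'
#' A generative model for continuous trajectories described in generalized
#' coordinates of motion: outcomes are generated from the hidden states (and
#' causes) by a static nonlinear mapping `g`, while the motion of hidden
#' states follows a flow `f` of states and causes, each with random
#' fluctuations whose inverse variances are the precisions `Pi_o` and
#' `Pi_x`. Hidden causes `v` carry a Gaussian prior `(eta, Pi_eta)`; in
#' mixed models this prior is installed by the link node.
#'
#' @param f Flow function `f(x, v)` returning the motion of hidden states
#'   (length `nx`). May be `NULL` when `nx = 0` (static models).
#' @param g Observation function `g(x, v)` returning predicted outcomes
#'   (length `no`).
#' @param nx,nv,no State, cause and outcome dimensionalities.
#' @param n_orders Embedding order of generalized motion (>= 1); order 1
#'   recovers the (extended) Kalman-filter limit.
#' @param Pi_o,Pi_x Outcome and state-noise precisions: a single SPD matrix
#'   (applied to order 0, with higher orders copied) or a list of length
#'   `n_orders`.
#' @param eta,Pi_eta Prior expectation and precision over hidden causes.
#' @param fx,fv,gx,gv Optional analytic Jacobians `(x, v) -> matrix`;
#'   computed by central finite differences when absent.
#' @return Object of class `continuous_model`.
#' @export
continuous_model <- function(f = NULL, g, nx, nv, no, n_orders = 2L,
                             Pi_o, Pi_x = NULL, eta = numeric(nv),
                             Pi_eta = diag(1, nv),
                             fx = NULL, fv = NULL, gx = NULL, gv = NULL) {
  as_prec_list <- function(P, dim, n) {
    if (dim == 0L) return(rep(list(matrix(0, 0L, 0L)), n))
    if (!is.list(P)) {
      P <- as.matrix(P)
      P <- rep(list(P), n)
    }
    lapply(P, function(p) {
      p <- as.matrix(p)
      if (!isTRUE(all.equal(p, t(p)))) stopf("precisions must be symmetric")
      p
    })
  }
  m <- structure(list(
    f = f, g = g, nx = as.integer(nx), nv = as.integer(nv),
    no = as.integer(no), n_orders = as.integer(n_orders),
    Pi_o = as_prec_list(Pi_o, no, n_orders),
    Pi_x = as_prec_list(Pi_x %||% diag(1, nx), nx, n_orders),
    eta = eta, Pi_eta = as.matrix(Pi_eta),
    fx = fx, fv = fv, gx = gx, gv = gv
  ), class = "continuous_model")
  m
}

#' @export
print.continuous_model <- function(x, ...) {
  cat(sprintf("<continuous_model: nx=%d nv=%d no=%d, %d generalized order(s)>\n",
              x$nx, x$nv, x$no, x$n_orders))
  invisible(x)
}

#' Initial generalized state for a continuous model
#'
#' @param model A [continuous_model()].
#' @param x0 Initial state expectation (order 0); defaults to zeros.
#' @param v0 Initial cause expectation; defaults to the prior mean.
#' @param a0 Initial action; defaults to zeros (dimension `na`).
#' @param na Number of action variables (default 0).
#' @return Object of class `generalized_state` with fields `mu_x`
#'   (`nx x n_orders`), `mu_v`, `a` and `F`.
#' @export
generalized_state <- function(model, x0 = NULL, v0 = NULL, a0 = NULL, na = 0L) {
  structure(list(
    mu_x = {
      mx <- matrix(0, model$nx, model$n_orders)
      if (!is.null(x0) && model$nx > 0L) mx[, 1L] <- x0
      mx
    },
    mu_v = v0 %||% model$eta,
    a = a0 %||% numeric(na),
    eps_x = NULL, eps_o = NULL, F = NA_real_
  ), class = "generalized_state")
}

#' Generalized shift operator
#'
#' `shift_gen` maps `(x, x', x'') -> (x', x'', 0)` (returns higher-order
#' motion); with `transpose = TRUE` it returns lower-order motion
#' `(x, x', x'') -> (0, x, x')`.
#'
#' @param x Matrix `n x n_orders` (or a vector, treated as one row per
#'   order for `n = 1`).
#' @param transpose Apply the transposed operator.
#' @return Shifted object of the same shape.
#' @export
#' @examples
#' shift_gen(matrix(c(1, 2, 3), 1))          # 2 3 0
#' shift_gen(matrix(c(1, 2, 3), 1), TRUE)    # 0 2 3
shift_gen <- function(x, transpose = FALSE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  k <- ncol(x)
  out <- matrix(0, nrow(x), k)
  if (k > 1L) {
    if (transpose) out[, 2:k] <- x[, 2:k] else out[, 1:(k - 1L)] <- x[, 2:k]
  }
  if (vec) out <- out[1L, ]
  out
}

num_jacobian <- function(fn, x, h = 1e-6) {
  n <- length(x)
  f0 <- fn(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (fn(x + e) - fn(x - e)) / (2 * h)
  }
  J
}

model_jacobians <- function(model, x, v) {
  fx <- fv <- gx <- gv <- NULL
  if (model$nx > 0L) {
    fx <- if (!is.null(model$fx)) model$fx(x, v) else
      num_jacobian(function(z) model$f(z, v), x)
    gx <- if (!is.null(model$gx)) model$gx(x, v) else
      num_jacobian(function(z) model$g(z, v), x)
    fx <- matrix(fx, model$nx, model$nx)
    gx <- matrix(gx, model$no, model$nx)
  } else {
    fx <- matrix(0, 0L, 0L)
    gx <- matrix(0, model$no, 0L)
  }
  if (model$nv > 0L) {
    fv <- if (!is.null(model$fv)) model$fv(x, v) else if (model$nx > 0L)
      num_jacobian(function(z) model$f(x, z), v) else matrix(0, 0L, model$nv)
    gv <- if (!is.null(model$gv)) model$gv(x, v) else
      num_jacobian(function(z) model$g(x, z), v)
    fv <- matrix(fv, model$nx, model$nv)
    gv <- matrix(gv, model$no, model$nv)
  } else {
    fv <- matrix(0, model$nx, 0L)
    gv <- matrix(0, model$no, 0L)
  }
  list(fx = fx, fv = fv, gx = gx, gv = gv)
}

#' Generalized prediction errors
#'
#' Computes the state and outcome prediction errors of generalized
#' filtering: `eps_x[i] = x[i+1] - f[i]` and `eps_o[i] = o[i] - g[i]`, where
#' the generalized flows and observation maps for orders `i >= 1` are
#' obtained by first-order (Jacobian) chain-rule propagation,
#' `f[i] = df/dx x[i]`.
#'
#' @param model A [continuous_model()].
#' @param mu_x Generalized state expectations (`nx x n_orders`).
#' @param mu_v Cause expectations.
#' @param obs Observed outcomes: matrix `no x n_orders` (higher orders may
#'   be zero when unobserved; give them zero precision in the model).
#' @return List with `eps_x` (`nx x n_orders`), `eps_o` (`no x n_orders`)
#'   and the Jacobians used.
#' @export
prediction_errors <- function(model, mu_x, mu_v, obs) {
  k <- model$n_orders
  J <- model_jacobians(model, if (model$nx) mu_x[, 1L] else numeric(0), mu_v)
  eps_x <- matrix(0, model$nx, k)
  eps_o <- matrix(0, model$no, k)
  obs <- matrix(obs, model$no, k)

  for (i in seq_len(k)) {
    gi <- if (i == 1L) model$g(if (model$nx) mu_x[, 1L] else numeric(0), mu_v) else
      if (model$nx) J$gx %*% mu_x[, i] else numeric(model$no)
    if (any(!is.finite(gi))) stopf("prediction_errors: non-finite observation function output")
    eps_o[, i] <- obs[, i] - gi
    if (model$nx > 0L) {
      fi <- if (i == 1L) model$f(mu_x[, 1L], mu_v) else J$fx %*% mu_x[, i]
      if (any(!is.finite(fi))) stopf("prediction_errors: non-finite flow output")
      x_next <- if (i < k) mu_x[, i + 1L] else numeric(model$nx)
      eps_x[, i] <- x_next - fi
    }
  }
  list(eps_x = eps_x, eps_o = eps_o, J = J)
}

# free energy and gradients of the generalized filter (instantaneous)
filter_gradients <- function(model, state, obs) {
  k <- model$n_orders
  pe <- prediction_errors(model, state$mu_x, state$mu_v, obs)
  J <- pe$J
  eps_v <- state$mu_v - model$eta

  Fe <- 0.5 * sum(eps_v * (model$Pi_eta %*% eps_v))
  for (i in seq_len(k)) {
    Fe <- Fe + 0.5 * sum(pe$eps_o[, i] * (model$Pi_o[[i]] %*% pe$eps_o[, i]))
    if (model$nx > 0L) {
      Fe <- Fe + 0.5 * sum(pe$eps_x[, i] * (model$Pi_x[[i]] %*% pe$eps_x[, i]))
    }
  }

  dFdx <- matrix(0, model$nx, k)
  if (model$nx > 0L) {
    for (i in seq_len(k)) {
      wo <- model$Pi_o[[i]] %*% pe$eps_o[, i]
      wx <- model$Pi_x[[i]] %*% pe$eps_x[, i]
      dFdx[, i] <- -crossprod(J$gx, wo) - crossprod(J$fx, wx)
      if (i > 1L) {
        dFdx[, i] <- dFdx[, i] + model$Pi_x[[i - 1L]] %*% pe$eps_x[, i - 1L]
      }
    }
  }
  wo0 <- model$Pi_o[[1L]] %*% pe$eps_o[, 1L]
  dFdv <- -crossprod(J$gv, wo0) + model$Pi_eta %*% eps_v
  if (model$nx > 0L) dFdv <- dFdv - crossprod(J$fv, model$Pi_x[[1L]] %*% pe$eps_x[, 1L])

  list(F = Fe, dFdx = dFdx, dFdv = as.numeric(dFdv), pe = pe)
}

#' One step of generalized (variational) filtering
#'
#' Integrates `mu_dot = Delta mu - dF/dmu` with an explicit Euler step: the
#' generalized gradient descent on variational free energy whose stationary
#' points satisfy "the motion of the mean is the mean of the motion". The
#' gradient is assembled analytically from the precision-weighted prediction
#' errors and Jacobians.
#'
#' @param model A [continuous_model()].
#' @param state A [generalized_state()].
#' @param obs Observed outcomes (`no x n_orders` matrix or length-`no`
#'   vector for order 0).
#' @param dt Integration step (> 0), in units of the model's time constant.
#' @param bound Divergence guard: error if any expectation magnitude exceeds
#'   it (default 1e6).
#' @param substeps Number of Euler micro-steps per call (observation held
#'   fixed). Stiff models - precise priors or fast flows relative to `dt` -
#'   need `dt * curvature < 2` for stability, which substepping restores
#'   without changing the sampling grid.
#' @return Updated [generalized_state()] with `F`, `eps_x`, `eps_o` filled.
#' @export
filter_step <- function(model, state, obs, dt, bound = 1e6, substeps = 1L) {
  stopifnot(dt > 0, substeps >= 1L)
  h <- dt / substeps
  gr <- NULL
  for (k in seq_len(substeps)) {
    gr <- filter_gradients(model, state, obs)
    if (model$nx > 0L) {
      state$mu_x <- state$mu_x + h * (shift_gen(state$mu_x) - gr$dFdx)
    }
    state$mu_v <- state$mu_v - h * gr$dFdv
    if (any(abs(state$mu_x) > bound) || any(abs(state$mu_v) > bound)) {
      stopf("filter_step: integration diverged (expectation exceeded bound)")
    }
  }
  state$F <- gr$F
  state$eps_x <- gr$pe$eps_x
  state$eps_o <- gr$pe$eps_o
  state
}

#' Update action by descending the outcome prediction error
#'
#' Action can only change outcomes, so its free-energy gradient involves
#' only the (precision-weighted) outcome prediction errors:
#' `a_dot = -(do/da)' Pi_o eps_o`.
#'
#' @param model A [continuous_model()].
#' @param state A [generalized_state()] with current `eps_o` (run
#'   [filter_step()] first).
#' @param process Process description exposing `do_da(x, a)`: the derivative
#'   of outcomes with respect to action (matrix `no x na`).
#' @param dt Integration step.
#' @param gain Action gain (default 1).
#' @return Updated state with the new action.
#' @export
action_update <- function(model, state, process, dt, gain = 1) {
  if (is.null(process$do_da)) stopf("action_update: process must expose do_da (structural error)")
  eps0 <- state$eps_o[, 1L]
  Jo <- process$do_da(state$mu_x, state$a)
  a_dot <- -gain * as.numeric(crossprod(Jo, model$Pi_o[[1L]] %*% eps0))
  state$a <- state$a + dt * a_dot
  state
}

#' Co-integrate a generative process and active generalized filter
#'
#' Runs the continuous action-perception loop: at each step the (seeded,
#' noisy) process generates outcomes as a function of its true states and
#' the current action; the filter assimilates them; action descends the
#' outcome prediction error. Fixed seeds give bitwise-reproducible
#' trajectories.
#'
#' @param model A [continuous_model()].
#' @param process List describing the true dynamics, with elements
#'   `f(x, a)` (true flow), `g(x)` (true observation map), `x0` (initial
#'   true state), `do_da` (for action), `sd_x`/`sd_o` (noise standard
#'   deviations, scalar or per-dimension) and optionally `na`.
#' @param steps Number of Euler steps.
#' @param dt Step size.
#' @param seed Seed for the process noise substream (ignored when `stream`
#'   is given).
#' @param stream Optional [rng_stream()].
#' @param state Optional initial [generalized_state()] (carried over between
#'   saccades in the reading model).
#' @param active Apply [action_update()] each step.
#' @param gain Action gain.
#' @param snapshot Optional function `(model, state, obs)` evaluated each
#'   step; results collected in `snapshots` (used for link-node evidence).
#' @return A `bp_trajectory` object: tibble `trace` (time, true states,
#'   expectations, action, free energy) plus final `state`, `x_true` and
#'   `snapshots`.
#' @export
integrate_active <- function(model, process, steps, dt, seed = 1L,
                             stream = NULL, state = NULL, active = TRUE,
                             gain = 1, snapshot = NULL, substeps = 1L) {
  if (is.null(stream)) stream <- rng_stream(seed)
  na <- process$na %||% length(process$x0)
  if (is.null(state)) state <- generalized_state(model, na = na)
  x <- process$x0
  sd_x <- rep(process$sd_x %||% 0, length.out = length(x))
  sd_o <- rep(process$sd_o %||% 0, length.out = model$no)

  rows <- vector("list", steps)
  snaps <- if (is.null(snapshot)) NULL else vector("list", steps)

  for (k in seq_len(steps)) {
    o <- process$g(x) + with_stream(stream, stats::rnorm(model$no, 0, sd_o))
    obs <- matrix(0, model$no, model$n_orders)
    obs[, 1L] <- o
    state <- filter_step(model, state, obs, dt, substeps = substeps)
    if (active) state <- action_update(model, state, process, dt, gain = gain)
    if (!is.null(snapshot)) snaps[[k]] <- snapshot(model, state, obs)

    rows[[k]] <- tibble::tibble(
      step = k, time = k * dt,
      x_true = list(x), o = list(o),
      mu_x = list(state$mu_x), mu_v = list(state$mu_v),
      a = list(state$a), F = state$F
    )
    # process dynamics (Euler-Maruyama)
    x <- x + dt * process$f(x, state$a) +
      sqrt(dt) * with_stream(stream, stats::rnorm(length(x), 0, sd_x))
  }

  structure(list(
    trace = dplyr::bind_rows(rows),
    state = state, x_true = x, snapshots = snaps,
    dt = dt, steps = steps
  ), class = "bp_trajectory")
}

#' @export
print.bp_trajectory <- function(x, ...) {
  cat(sprintf("<bp_trajectory: %d step(s), dt = %.4g, final F = %.4g>\n",
              x$steps, x$dt, x$state$F))
  invisible(x)
}

#' Eigenvalues of the free-energy curvature
#'
#' Finite-difference curvature (Hessian) of variational free energy in the
#' generalized expectations; near a free-energy minimum all eigenvalues are
#' positive, and their magnitudes play the role of (negative) Lyapunov
#' exponents: small curvature means critical slowing.
#'
#' @param model A [continuous_model()].
#' @param state A [generalized_state()] near a stationary point.
#' @param obs Observations held fixed during differentiation.
#' @param h Finite-difference step (default 1e-4).
#' @param sym_tol Warn when the numerical Hessian is asymmetric beyond this
#'   relative tolerance (default 1e-4).
#' @return Numeric vector of eigenvalues (decreasing).
#' @export
curvature_spectrum <- function(model, state, obs, h = 1e-4, sym_tol = 1e-4) {
  pack <- function(st) c(as.numeric(st$mu_x), st$mu_v)
  unpack <- function(mu) {
    st <- state
    nmx <- model$nx * model$n_orders
    if (nmx > 0L) st$mu_x <- matrix(mu[seq_len(nmx)], model$nx, model$n_orders)
    st$mu_v <- mu[nmx + seq_len(model$nv)]
    st
  }
  f_of <- function(mu) filter_gradients(model, unpack(mu), obs)$F
  mu0 <- pack(state)
  n <- length(mu0)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      ei <- numeric(n); ei[i] <- h
      ej <- numeric(n); ej[j] <- h
      H[i, j] <- (f_of(mu0 + ei + ej) - f_of(mu0 + ei - ej) -
                  f_of(mu0 - ei + ej) + f_of(mu0 - ei - ej)) / (4 * h^2)
      H[j, i] <- H[i, j]
    }
  }
  eigen(H, symmetric = TRUE, only.values = TRUE)$values
}
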
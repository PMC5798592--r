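#' Specify a discrete (Markov decision process) generative model
#'
#' A discrete generative model is defined by a likelihood mapping `A` from
#' hidden states to outcomes, action-conditioned state transitions `B`, log
#' prior preferences `C` over outcomes, priors `D` over initial states, a set
#' of `policies` (action sequences) and a planning horizon `T`. Several hidden
#' state factors are supported; the likelihood is indexed by the cross product
#' of the factors (factor 1 varies fastest, i.e. column-major flattening).
#' Several outcome modalities are supported as a list of `A` arrays sharing
#' the state index.
#'
#' @param A Likelihood: a matrix/array with first dimension the outcomes of a
#'   modality and remaining dimensions the state factors, or a list of such
#'   arrays (one per modality). Columns (over the joint state index) must be
#'   probability distributions.
#' @param B Transitions: a 3-d array `(next state, state, action)` for a
#'   single factor, or a list of such arrays (one per factor). Factors that
#'   are never acted on may supply a single-slice array.
#' @param C Log preferences over outcomes: per modality either a vector
#'   (broadcast over time) or an `outcomes x T` matrix. Defaults to zeros
#'   (no pragmatic preference, purely epistemic behaviour).
#' @param D Prior over initial states: a probability vector per factor (a
#'   list for several factors). In deep models the empirical prior that
#'   replaces `D` is produced by [descending_message()].
#' @param policies Integer array `(transitions x policies x controlled
#'   factors)` of 1-based action indices, together with `control` giving the
#'   indices of the controlled factors. Defaults to the single "do nothing"
#'   policy (action 1 everywhere).
#' @param control Integer vector: which state factors the policies control.
#' @param T Planning horizon (number of epochs). Defaults to
#'   `nrow(policies) + 1`.
#' @param H Optional outcome-ambiguity vector over joint states (nats);
#'   computed with [ambiguity()] from `A` when not supplied.
#' @param label Optional model name used in printing.
#'
#' @return An object of class `discrete_model`.
#' @seealso [validate_model()], [run_trial()], [ambiguity()]
#' @export
#' @examples
#' m <- discrete_model(
#'   A = diag(2), B = array(diag(2), c(2, 2, 1)), D = c(0.5, 0.5), T = 2
#' )
#' validate_model(m)$ok
discrete_model <- function(A, B, C = NULL, D, policies = NULL, control = NULL,
                           T = NULL, H = NULL, label = NULL) {
  if (!is.list(A)) A <- list(A)
  if (!is.list(B)) B <- list(B)
  if (!is.list(D)) D <- list(D)
  B <- lapply(B, function(b) if (length(dim(b)) == 2L) array(b, c(dim(b), 1L)) else b)

  n_states <- vapply(D, length, integer(1))
  n_joint <- prod(n_states)
  # flatten each modality's likelihood onto the joint state index
  A <- lapply(A, function(a) {
    am <- if (is.null(dim(a))) matrix(a, nrow = 1L) else matrix(a, nrow = dim(a)[1L])
    am
  })
  n_out <- vapply(A, nrow, integer(1))

  if (is.null(policies)) {
    nt <- max(1L, (T %||% 2L) - 1L)
    policies <- array(1L, c(nt, 1L, 0L))
    control <- integer(0)
  }
  if (length(dim(policies)) == 2L) policies <- array(policies, c(dim(policies), 1L))
  if (is.null(control)) control <- seq_len(dim(policies)[3L])
  if (is.null(T)) T <- dim(policies)[1L] + 1L

  C <- normalise_C(C, n_out, T)

  m <- structure(list(
    A = A, B = B, C = C, D = D,
    policies = policies, control = as.integer(control),
    T = as.integer(T),
    n_states = n_states, n_joint = n_joint,
    n_out = n_out, n_modalities = length(A),
    n_factors = length(D), n_policies = dim(policies)[2L],
    label = label
  ), class = "discrete_model")
  m$H <- H %||% ambiguity(m$A)
  m
}

normalise_C <- function(C, n_out, T) {
  if (is.null(C)) C <- lapply(n_out, function(n) matrix(0, n, T))
  if (!is.list(C)) C <- list(C)
  mapply(function(cm, n) {
    if (is.null(dim(cm))) cm <- matrix(cm, n, T)
    if (ncol(cm) == 1L) cm <- matrix(cm[, 1L], n, T)
    cm
  }, C, n_out, SIMPLIFY = FALSE)
}

#' @export
print.discrete_model <- function(x, ...) {
  cat(sprintf(
    "<discrete_model%s: %d state factor(s) [%s], %d modality(ies) [%s], %d policy(ies), T = %d>\n",
    if (is.null(x$label)) "" else paste0(" ", x$label),
    x$n_factors, paste(x$n_states, collapse = "x"),
    x$n_modalities, paste(x$n_out, collapse = ","),
    x$n_policies, x$T
  ))
  invisible(x)
}

#' Normalize the columns of a probability array
#'
#' Applies the column-stochastic convention for conditional probability
#' tables: `A[i, j] <- A[i, j] / sum_k A[k, j]`. For a 3-d transition array
#' every action slice is normalized.
#'
#' @param x Nonnegative matrix or 3-d array.
#' @return Column-stochastic object of the same shape.
#' @export
#' @examples
#' normalize_columns(matrix(c(1, 1, 0, 2), 2))
normalize_columns <- function(x) {
  if (any(x < 0)) stopf("normalize_columns: negative entries")
  if (length(dim(x)) == 3L) {
    for (k in seq_len(dim(x)[3L])) x[, , k] <- normalize_columns(x[, , k])
    return(x)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  cs <- colSums(x)
  if (any(cs == 0)) stopf("normalize_columns: all-zero column (degenerate input)")
  sweep(x, 2L, cs, "/")
}

# transpose-normalized mapping: rows of x normalized, then transposed
# ("backward matrix multiplication" convention)
bt_normalize <- function(x) {
  rs <- rowSums(x)
  rs[rs == 0] <- 1
  t(x / rs)
}

#' Outcome ambiguity per hidden state
#'
#' The conditional entropy of outcomes given each (joint) hidden state,
#' summed over outcome modalities:
#' `H_j = sum_m -sum_i A_m[i, j] * log A_m[i, j]` (nats), with the shared
#' log-floor rule ([ln_safe()]) so that deterministic likelihoods give zero.
#'
#' @param A A column-stochastic likelihood matrix, or a list of them (one per
#'   modality, sharing the joint state index).
#' @return Numeric vector of ambiguities, one per joint state.
#' @export
#' @examples
#' ambiguity(matrix(0.5, 2, 2))  # ln 2 per state
ambiguity <- function(A) {
  if (!is.list(A)) A <- list(A)
  A <- lapply(A, function(a) if (is.null(dim(a))) matrix(a, nrow = 1L) else
    matrix(a, nrow = dim(a)[1L]))
  Reduce(`+`, lapply(A, function(a) -colSums(a * ln_safe(a))))
}

#' Validate a discrete generative model
#'
#' Checks the structural invariants of a [discrete_model()]: likelihood and
#' transition columns sum to one (within 1e-10) with nonnegative entries,
#' initial-state priors sum to one, policy action indices are valid for the
#' factor they control, and the ambiguity vector is nonnegative.
#'
#' @param model A [discrete_model()].
#' @return A list with elements `ok` (logical) and `problems` (character
#'   vector naming each violated invariant, empty when `ok`).
#' @export
validate_model <- function(model) {
  problems <- character(0)
  tol <- 1e-10

  if (model$n_joint != prod(model$n_states)) {
    problems <- c(problems, "joint state count does not match factor cardinalities")
  }
  for (m in seq_along(model$A)) {
    a <- model$A[[m]]
    if (ncol(a) != model$n_joint) {
      problems <- c(problems, sprintf(
        "A[%d]: %d state columns but factors imply %d (structural error)",
        m, ncol(a), model$n_joint))
      next
    }
    if (any(a < 0)) problems <- c(problems, sprintf("A[%d]: negative entries", m))
    bad <- which(abs(colSums(a) - 1) > tol)
    if (length(bad)) problems <- c(problems, sprintf(
      "A[%d]: column(s) %s do not sum to 1", m, paste(utils::head(bad, 5L), collapse = ",")))
  }
  for (f in seq_along(model$B)) {
    b <- model$B[[f]]
    if (!all(dim(b)[1:2] == model$n_states[f])) {
      problems <- c(problems, sprintf("B[%d]: dimensions do not match factor size", f))
      next
    }
    if (any(b < 0)) problems <- c(problems, sprintf("B[%d]: negative entries", f))
    for (k in seq_len(dim(b)[3L])) {
      bad <- which(abs(colSums(b[, , k, drop = FALSE][, , 1L]) - 1) > tol)
      if (length(bad)) problems <- c(problems, sprintf(
        "B[%d] action %d: column(s) %s do not sum to 1",
        f, k, paste(utils::head(bad, 5L), collapse = ",")))
    }
  }
  for (f in seq_along(model$D)) {
    d <- model$D[[f]]
    d <- as.matrix(d)
    if (any(d < 0)) problems <- c(problems, sprintf("D[%d]: negative entries", f))
    bad <- which(abs(colSums(d) - 1) > tol)
    if (length(bad)) problems <- c(problems, sprintf(
      "D[%d]: column(s) %s do not sum to 1", f, paste(bad, collapse = ",")))
  }
  if (length(model$control)) {
    for (j in seq_along(model$control)) {
      f <- model$control[j]
      n_act <- dim(model$B[[f]])[3L]
      acts <- model$policies[, , j, drop = FALSE]
      if (any(acts < 1L | acts > n_act)) {
        problems <- c(problems, sprintf(
          "policies: invalid action index for factor %d (valid 1..%d)", f, n_act))
      }
    }
  }
  if (any(model$H < -1e-12)) problems <- c(problems, "H: negative ambiguity")

  list(ok = length(problems) == 0L, problems = problems)
}

# ---- joint-space helpers ------------------------------------------------

# joint initial prior (outer product over factors; factor 1 fastest)
joint_D <- function(model, D_override = NULL) {
  D <- model$D
  if (!is.null(D_override)) {
    for (f in seq_along(D_override)) {
      if (!is.null(D_override[[f]])) D[[f]] <- D_override[[f]]
    }
  }
  Reduce(kronecker, rev(D))
}

# joint transition matrix for policy p at transition t
joint_B <- function(model, policy, t) {
  slices <- vector("list", model$n_factors)
  for (f in seq_len(model$n_factors)) {
    a <- 1L
    j <- match(f, model$control)
    if (!is.na(j)) a <- model$policies[t, policy, j]
    slices[[f]] <- model$B[[f]][, , a]
  }
  Reduce(kronecker, rev(slices))
}

# marginal of a joint-state probability vector onto factor f
factor_marginal <- function(p, n_states, f) {
  arr <- array(p, n_states)
  apply(arr, f, sum)
}

# joint state index from per-factor indices (factor 1 fastest)
joint_index <- function(states, n_states) {
  idx <- states[1L]
  mult <- 1L
  for (f in seq_along(states)[-1L]) {
    mult <- mult * n_states[f - 1L]
    idx <- idx + (states[f] - 1L) * mult
  }
  idx
}
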
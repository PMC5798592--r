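#' Numerically safe natural logarithm
#'
#' Log with a floor at `exp(-16)`: `ln_safe(x) = log(max(x, exp(-16)))`.
#' This prevents `-Inf` when taking logs of vanishing expectations while
#' leaving every probability above ~1.1e-7 untouched, so message passing in
#' regimes where all quantities are bounded away from zero is exact.
#'
#' @param x Numeric vector, matrix or array of nonnegative values.
#' @return Object of the same shape with the floored logarithm applied.
#' @export
#' @examples
#' ln_safe(c(0, 1e-3, 1))
ln_safe <- function(x) log(pmax(x, exp(-16)))

#' Softmax (normalized exponential)
#'
#' @param x Numeric vector of log-space values (nats).
#' @return Probability vector summing to one.
#' @export
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# entropy of a categorical distribution, 0 ln 0 = 0 convention
cat_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

norm_vec <- function(x) x / sum(x)

one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create an independent random-number substream
#'
#' Process-side sampling (environment dynamics, sensory noise) consumes a
#' named substream so that model-side computations are unaffected by how many
#' random draws the process makes. The stream stores its own `.Random.seed`
#' and swaps it in and out around each draw.
#'
#' @param seed Integer seed for the substream.
#' @return An environment of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$state <- NULL
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression using a substream's RNG state
#'
#' @param stream An [rng_stream()].
#' @param expr Expression to evaluate with the stream's RNG state installed.
#' @return The value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(stream$state)) {
    set.seed(stream$seed)
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# sample one categorical index from a probability vector
sample_cat <- function(p) {
  p <- p / sum(p)
  min(findInterval(stats::runif(1), cumsum(p)) + 1L, length(p))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
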
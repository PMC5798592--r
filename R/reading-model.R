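#' Default configuration of the reading simulation
#'
#' Every default is overridable; see the methods vignette for the rationale
#' behind each value.
#'
#' @param ... Named overrides, nested lists merged into the defaults (e.g.
#'   `timing = list(steps_per_saccade = 12)`).
#' @return Nested configuration list.
#' @export
reading_config <- function(...) {
  defaults <- list(
    world = list(attenuation_sigma = 0.35, true_sentence = 1L,
                 true_flips = c(1L, 1L), glyph_seed = 1L),
    level1 = list(T = 2L, gamma = 8, iterations = 16L, step = 0.25),
    level2 = list(T = 4L, iterations = 16L, step = 0.25),
    link = list(pi_L = 16, pi_I = 32),
    continuous = list(n_orders = 2L, tau = 0.25, pi_prop = 32, pi_vis = 8,
                      pi_x = 8, gain = 16, substeps = 8L,
                      sd_prop = 0.02, sd_vis = sqrt(1 / 8), sd_x = 0.02),
    timing = list(steps_per_saccade = 24L, dt = 1 / 24, bin_ms = 256 / 24),
    ephys = list(band_hz = c(4, 32), order = 4L)
  )
  utils::modifyList(defaults, list(...))
}

#' Build the two-level reading model, its link and continuous level
#'
#' Constructs the full generative hierarchy of the reading simulation:
#' a second discrete level over sentence (6) x word-position (4) generating
#' word outcomes; a first discrete level over word (3) x quadrant (4) x
#' vertical flip (2) x horizontal flip (2) generating letter (what) and
#' fixation (where) outcomes; the link specification whose outcome models
#' are \{glyph identity\} x \{quadrant target\} Gaussian priors over the
#' continuous hidden causes; and the continuous oculomotor model in which
#' gaze is attracted to the target cause while visual features are the
#' contrast-attenuated glyph features.
#'
#' @param config A [reading_config()].
#' @return List with `level2`, `level1` (models), `level2_process`,
#'   `level1_process_fn`, `link_models`, `continuous` (a
#'   [continuous_model()]), `world` and `config`.
#' @export
build_reading_model <- function(config = reading_config()) {
  world <- reading_world(attenuation_sigma = config$world$attenuation_sigma,
                         true_sentence = config$world$true_sentence,
                         true_flips = config$world$true_flips,
                         glyph_seed = config$world$glyph_seed)
  layouts <- world$word_layouts

  ## ---- level 1: word x quadrant x vflip x hflip -> letter, fixation ----
  n1 <- c(3L, 4L, 2L, 2L)
  nj1 <- prod(n1)
  A_what <- matrix(0, 4L, nj1)
  A_where <- matrix(0, 4L, nj1)
  idx <- 1L
  for (hf in 1:2) for (vf in 1:2) for (q in 1:4) for (w in 1:3) {
    # factor 1 (word) varies fastest to match the joint flattening
    j <- joint_index(c(w, q, vf, hf), n1)
    A_what[layouts[w, vf, hf, q], j] <- 1
    A_where[q, j] <- 1
    idx <- idx + 1L
  }
  B_word <- array(diag(3), c(3, 3, 1))
  B_quad <- array(0, c(4, 4, 4))
  for (a in 1:4) B_quad[a, , a] <- 1          # action a moves gaze to quadrant a
  B_flip <- array(diag(2), c(2, 2, 1))
  policies1 <- array(rep(1:4, each = 1L), c(1L, 4L, 1L))
  level1 <- discrete_model(
    A = list(what = A_what, where = A_where),
    B = list(B_word, B_quad, B_flip, B_flip),
    D = list(rep(1 / 3, 3), c(1, 0, 0, 0), c(0.5, 0.5), c(0.5, 0.5)),
    policies = policies1, control = 2L, T = config$level1$T,
    label = "reading level 1"
  )

  ## ---- level 2: sentence x position -> word, position ------------------
  n2 <- c(6L, 4L)
  A_word <- matrix(0, 3L, prod(n2))
  A_pos <- matrix(0, 4L, prod(n2))
  for (p in 1:4) for (s in 1:6) {
    j <- joint_index(c(s, p), n2)
    A_word[world$sentences[s, p], j] <- 1
    A_pos[p, j] <- 1
  }
  B_sent <- array(diag(6), c(6, 6, 1))
  advance <- matrix(0, 4, 4)
  for (p in 1:4) advance[min(p + 1L, 4L), p] <- 1
  B_pos <- array(advance, c(4, 4, 1))
  level2 <- discrete_model(
    A = list(word = A_word, position = A_pos),
    B = list(B_sent, B_pos),
    D = list(rep(1 / 6, 6), c(1, 0, 0, 0)),
    policies = array(1L, c(3L, 1L, 0L)), control = integer(0),
    T = config$level2$T, label = "reading level 2"
  )

  ## ---- processes (same A and B as the models; D is the configuration) --
  stopifnot(identical(level1$A[[1]], A_what), identical(level2$A[[1]], A_word))
  level2_process <- discrete_model(
    A = level2$A, B = level2$B,
    D = list(one_hot(world$true_sentence, 6L), c(1, 0, 0, 0)),
    policies = level2$policies, control = level2$control, T = level2$T
  )
  level1_process_fn <- function(t, hi_true_states, stream) {
    true_word <- world$sentences[hi_true_states[1L], hi_true_states[2L]]
    discrete_model(
      A = level1$A, B = level1$B,
      D = list(one_hot(true_word, 3L), c(1, 0, 0, 0),
               one_hot(world$true_flips[1L], 2L),
               one_hot(world$true_flips[2L], 2L)),
      policies = level1$policies, control = level1$control, T = level1$T
    )
  }

  ## ---- link: outcome models = glyph identity x quadrant target ---------
  cc <- config$continuous
  phi <- world$features
  link_models <- vector("list", 16L)
  for (q in 1:4) for (g in 1:4) {
    link_models[[g + 4L * (q - 1L)]] <- list(
      eta = c(world$quadrant_centers[q, ], phi[[g]]),
      Pi = diag(c(rep(config$link$pi_L, 2L), rep(config$link$pi_I, 16L))),
      glyph = g, quadrant = q
    )
  }

  ## ---- continuous oculomotor model -------------------------------------
  sig2 <- world$attenuation_sigma^2
  tau <- cc$tau
  g_fun <- function(x, v) {
    d <- x - v[1:2]
    c(x, exp(-sum(d^2) / (2 * sig2)) * v[-(1:2)])
  }
  f_fun <- function(x, v) (v[1:2] - x) / tau
  gx <- function(x, v) {
    d <- x - v[1:2]
    att <- exp(-sum(d^2) / (2 * sig2))
    rbind(diag(2), outer(v[-(1:2)], -d / sig2 * att))
  }
  gv <- function(x, v) {
    d <- x - v[1:2]
    att <- exp(-sum(d^2) / (2 * sig2))
    rbind(matrix(0, 2, 18),
          cbind(outer(v[-(1:2)], d / sig2 * att), att * diag(16)))
  }
  fx <- function(x, v) -diag(2) / tau
  fv <- function(x, v) cbind(diag(2) / tau, matrix(0, 2, 16))
  continuous <- continuous_model(
    f = f_fun, g = g_fun, nx = 2L, nv = 18L, no = 18L,
    n_orders = cc$n_orders,
    Pi_o = lapply(seq_len(cc$n_orders), function(i) {
      if (i == 1L) diag(c(rep(cc$pi_prop, 2), rep(cc$pi_vis, 16))) else
        diag(1e-8, 18)
    }),
    Pi_x = diag(cc$pi_x, 2),
    eta = numeric(18L), Pi_eta = diag(1, 18L),
    fx = fx, fv = fv, gx = gx, gv = gv
  )

  list(level2 = level2, level1 = level1,
       level2_process = level2_process,
       level1_process_fn = level1_process_fn,
       link_models = link_models, continuous = continuous,
       world = world, config = config)
}

# continuous process for one saccade: true glyph + true target, action moves gaze
make_saccade_process <- function(world, config, glyph, quadrant, x0) {
  cc <- config$continuous
  sig2 <- world$attenuation_sigma^2
  L <- world$quadrant_centers[quadrant, ]
  phi <- world$features[[glyph]]
  list(
    f = function(x, a) a,
    g = function(x) {
      d <- x - L
      c(x, exp(-sum(d^2) / (2 * sig2)) * phi)
    },
    do_da = function(mu_x, a) rbind(diag(2), matrix(0, 16, 2)),
    x0 = x0, na = 2L,
    sd_x = cc$sd_x, sd_o = c(rep(cc$sd_prop, 2), rep(cc$sd_vis, 16)),
    target = L, glyph = glyph, quadrant = quadrant
  )
}

#' Run the full reading simulation
#'
#' Executes the complete deep hierarchy: for each of the four words the
#' second level emits a descending empirical prior over the word, the first
#' level runs its epochs, and each first-level fixation is realized as one
#' continuous window (a saccade of `steps_per_saccade` integration steps,
#' about 256 ms) through the link node: the predicted what/where outcomes
#' set the categorical prior over the 16 outcome models, gaze is attracted
#' to the commanded quadrant center, visual features accumulate evidence,
#' and the ascending posterior over models is returned as the first level's
#' observed outcome. Simulated electrophysiology is assembled from the
#' per-iteration Bayesian model averages.
#'
#' @param seed Integer seed for all process randomness.
#' @param config A [reading_config()].
#' @return A `bp_reading` object with fields `deep` (the nested
#'   [run_deep()] record), `saccades` (tibble of per-saccade summaries),
#'   `trajectories` (list of `bp_trajectory`), `ephys` (an `bp_ephys`
#'   record), `world` and `config`.
#' @export
run_reading <- function(seed = 1L, config = reading_config()) {
  rm_ <- build_reading_model(config)
  world <- rm_$world
  tcfg <- rm_$config$timing

  gaze_env <- new.env(parent = emptyenv())
  gaze_env$x <- c(0, 0)              # central fixation at the start
  gaze_env$state <- NULL             # generalized filter state carried over
  gaze_env$saccades <- list()
  gaze_env$trajectories <- list()

  A_what <- rm_$level1$A[[1L]]
  n1 <- rm_$level1$n_states

  observe_fn <- function(t, pred, true_states, strm) {
    q <- true_states[2L]
    glyph <- which(A_what[, joint_index(true_states, n1)] == 1)
    # categorical prior over outcome models: predicted glyph x commanded
    # quadrant (efference copy makes the where component definitive)
    prior_o <- as.numeric(outer(pmax(pred[[1L]], exp(-16)), one_hot(q, 4L) + exp(-16)))
    prior_o <- prior_o / sum(prior_o)
    link <- link_spec(rm_$link_models, prior_o)
    proc <- make_saccade_process(world, rm_$config, glyph, q, gaze_env$x)
    st <- generalized_state(rm_$continuous, x0 = gaze_env$x, na = 2L)
    lc <- link_cycle(link, rm_$continuous, proc,
                     steps = tcfg$steps_per_saccade, dt = tcfg$dt,
                     stream = strm, state = st,
                     gain = rm_$config$continuous$gain,
                     substeps = rm_$config$continuous$substeps)
    post <- matrix(lc$posterior_o, 4L, 4L)      # glyph x quadrant
    what_post <- norm_vec(rowSums(post))
    where_post <- norm_vec(colSums(post))
    gaze_env$x <- lc$trajectory$x_true
    sac <- tibble::tibble(
      word = NA_integer_, epoch = t,
      target_quadrant = q,
      target_x = proc$target[1L], target_y = proc$target[2L],
      final_x = lc$trajectory$x_true[1L], final_y = lc$trajectory$x_true[2L],
      gaze_error = sqrt(sum((lc$trajectory$x_true - proc$target)^2)),
      true_glyph = glyph, decoded_glyph = which.max(what_post),
      p_true_glyph = what_post[glyph]
    )
    gaze_env$saccades <- c(gaze_env$saccades, list(sac))
    gaze_env$trajectories <- c(gaze_env$trajectories, list(lc$trajectory))
    list(obs = list(what_post, where_post),
         extra = list(link = lc$link, posterior_o = lc$posterior_o))
  }

  interfaces <- list(list(modality = 1L, factor = 1L, D = diag(3)))
  deep <- run_deep(
    hi = rm_$level2, lo = rm_$level1, interfaces = interfaces,
    hi_process = rm_$level2_process,
    lo_process_fn = rm_$level1_process_fn,
    lo_observe_fn = observe_fn,
    seed = seed,
    iterations = rm_$config$level2$iterations,
    step = rm_$config$level2$step,
    gamma = rm_$config$level1$gamma,
    record_iterations = TRUE
  )

  saccades <- dplyr::bind_rows(gaze_env$saccades)
  per_word <- rm_$level1$T
  saccades$word <- rep(seq_len(rm_$level2$T), each = per_word)
  saccades$saccade <- seq_len(nrow(saccades))

  ephys <- simulate_ephys(deep, bin_ms = tcfg$bin_ms,
                          band_hz = rm_$config$ephys$band_hz,
                          order = rm_$config$ephys$order,
                          steps_per_saccade = tcfg$steps_per_saccade)

  structure(list(
    deep = deep, saccades = saccades,
    trajectories = gaze_env$trajectories,
    ephys = ephys, world = world, config = rm_$config,
    model = rm_
  ), class = "bp_reading")
}

#' @export
print.bp_reading <- function(x, ...) {
  final <- x$deep$bma[[x$deep$T]][, 1L]
  sent <- factor_marginal(final, x$deep$model$n_states, 1L)
  cat(sprintf("<bp_reading: %d saccade(s); P(sentence %d) = %.3f (true %d)>\n",
              nrow(x$saccades), which.max(sent), max(sent), x$world$true_sentence))
  invisible(x)
}

#' Sentence-posterior summary of a reading run
#'
#' @param run A `bp_reading` object.
#' @return Tibble with one row per word completion: the sentence-level
#'   Bayesian model average (posterior over the six sentences), its entropy
#'   and the most probable sentence.
#' @export
sentence_posterior <- function(run) {
  hi <- run$deep$model
  purrr::map_dfr(seq_len(run$deep$T), function(t) {
    p <- factor_marginal(run$deep$bma[[t]][, 1L], hi$n_states, 1L)
    tibble::tibble(word = t, sentence = list(p),
                   entropy = cat_entropy(p), map = which.max(p),
                   p_true = p[run$world$true_sentence])
  })
}
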
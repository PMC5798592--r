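#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a discrete trial record
#'
#' @param x A `bp_trial` from [run_trial()].
#' @param ... Unused.
#' @return A tibble with one row per epoch x policy: the policy posterior
#'   `pi`, expected free energy `G` and final variational free energy `F`.
#' @export
tidy.bp_trial <- function(x, ...) {
  n_pol <- nrow(x$pi)
  purrr::map_dfr(seq_len(x$T), function(t) {
    tibble::tibble(
      epoch = t, policy = seq_len(n_pol),
      pi = x$pi[, t], G = x$G[, t],
      F = if (!is.null(x$F)) x$F[[t]] else NA_real_
    )
  })
}

#' One-row summary of a discrete trial
#'
#' @param x A `bp_trial`.
#' @param ... Unused.
#' @return A tibble with the number of epochs, policies and joint states,
#'   the entropy of the final policy posterior, the final free energy and
#'   whether the posterior tracked the true states (argmax agreement).
#' @export
glance.bp_trial <- function(x, ...) {
  last_bma <- x$bma[[x$T]]
  map_states <- apply(last_bma, 2L, which.max)
  true_joint <- vapply(seq_len(x$T), function(t)
    joint_index(x$true_states[, t], x$model$n_states), numeric(1))
  tibble::tibble(
    epochs = x$T,
    policies = nrow(x$pi),
    joint_states = x$model$n_joint,
    pi_entropy = cat_entropy(x$pi[, x$T]),
    F_final = if (!is.null(x$F)) sum(x$F[[x$T]] * x$pi[, x$T]) else NA_real_,
    state_accuracy = mean(map_states == true_joint)
  )
}

#' Plot policy posterior and free-energy traces of a trial
#'
#' @param object A `bp_trial`.
#' @param ... Unused.
#' @return A ggplot: policy posterior per epoch (tiles) over the trial.
#' @export
autoplot.bp_trial <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = factor(.data$policy),
                                   fill = .data$pi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black", limits = c(0, 1)) +
    ggplot2::labs(x = "epoch", y = "policy", fill = "posterior",
                  title = "Policy posterior over the trial") +
    ggplot2::theme_minimal()
}

#' Tidy a continuous trajectory
#'
#' @param x A `bp_trajectory` from [integrate_active()].
#' @param ... Unused.
#' @return A tibble with one row per step: time, true states (`x_true_*`),
#'   state expectations (`mu_x_*`, order 0), actions (`a_*`) and free
#'   energy.
#' @export
tidy.bp_trajectory <- function(x, ...) {
  tr <- x$trace
  nx <- length(tr$x_true[[1L]])
  na <- length(tr$a[[1L]])
  out <- tibble::tibble(step = tr$step, time = tr$time, F = tr$F)
  nmx <- nrow(tr$mu_x[[1L]])
  for (i in seq_len(nx)) {
    out[[paste0("x_true_", i)]] <- vapply(tr$x_true, `[`, numeric(1), i)
    out[[paste0("mu_x_", i)]] <- if (i <= nmx) {
      vapply(tr$mu_x, function(m) m[i, 1L], numeric(1))
    } else NA_real_
  }
  for (i in seq_len(na)) {
    out[[paste0("a_", i)]] <- vapply(tr$a, `[`, numeric(1), i)
  }
  out
}

#' Plot a continuous trajectory (true vs estimated states over time)
#'
#' @param object A `bp_trajectory`.
#' @param ... Unused.
#' @return A ggplot of true states and their expectations per dimension.
#' @export
autoplot.bp_trajectory <- function(object, ...) {
  df <- tidy(object)
  nx <- sum(grepl("^x_true_", names(df)))
  long <- purrr::map_dfr(seq_len(nx), function(i) {
    tibble::tibble(time = df$time, dim = paste0("x", i),
                   true = df[[paste0("x_true_", i)]],
                   estimate = df[[paste0("mu_x_", i)]])
  }) |>
    dplyr::filter(!is.na(.data$true)) |>
    tidyr::pivot_longer(c("true", "estimate"), names_to = "kind")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~dim, scales = "free_y") +
    ggplot2::labs(x = "time", y = "state",
                  title = "Generalized filtering: true vs expected states") +
    ggplot2::theme_minimal()
}

#' Tidy an electrophysiology record
#'
#' @param x A `bp_ephys` from [simulate_ephys()].
#' @param ... Unused.
#' @return A long tibble: one row per unit x bin with firing rate and LFP.
#' @export
tidy.bp_ephys <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$raster)), function(i) {
    tibble::tibble(
      unit = x$unit_labels[i], level = x$unit_level[i],
      time_s = x$time_s, rate = x$raster[i, ], lfp = x$lfp[i, ]
    )
  })
}

#' Plot simulated rasters and local field potentials
#'
#' Reproduces the standard layout: firing-rate rasters per level (darker =
#' higher rate), band-passed traces below, saccade onsets as dashed lines.
#'
#' @param object A `bp_ephys`.
#' @param ... Unused.
#' @return A patchwork-free single ggplot (faceted).
#' @export
autoplot.bp_ephys <- function(object, ...) {
  df <- tidy(object)
  df_long <- tidyr::pivot_longer(df, c("rate", "lfp"), names_to = "panel")
  df_long$panel <- factor(df_long$panel, levels = c("rate", "lfp"),
                          labels = c("firing rate", "LFP (band-passed)"))
  ons <- tibble::tibble(time_s = object$saccade_onsets_s)
  ggplot2::ggplot(df_long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                        colour = .data$unit)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = ons, ggplot2::aes(xintercept = .data$time_s),
                        linetype = "dashed", colour = "grey50", linewidth = 0.2) +
    ggplot2::facet_grid(panel ~ ., scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Simulated electrophysiology during reading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Tidy a reading simulation
#'
#' @param x A `bp_reading` from [run_reading()].
#' @param ... Unused.
#' @return The per-saccade summary tibble (targets, landing positions,
#'   gaze errors, decoded glyphs).
#' @export
tidy.bp_reading <- function(x, ...) x$saccades

#' One-row summary of a reading simulation
#'
#' @param x A `bp_reading`.
#' @param ... Unused.
#' @return A tibble: number of saccades, final posterior probability of the
#'   generating sentence, whether it is the maximum a posteriori sentence,
#'   maximum landing error and final sentence-posterior entropy.
#' @export
glance.bp_reading <- function(x, ...) {
  sp <- sentence_posterior(x)
  tibble::tibble(
    saccades = nrow(x$saccades),
    p_true_sentence = sp$p_true[nrow(sp)],
    map_correct = sp$map[nrow(sp)] == x$world$true_sentence,
    max_gaze_error = max(x$saccades$gaze_error),
    final_entropy = sp$entropy[nrow(sp)]
  )
}

#' Plot the eye-movement trajectory of a reading simulation
#'
#' @param object A `bp_reading`.
#' @param ... Unused.
#' @return A ggplot of the gaze path across saccades with quadrant targets.
#' @export
autoplot.bp_reading <- function(object, ...) {
  paths <- purrr::map_dfr(seq_along(object$trajectories), function(i) {
    df <- tidy(object$trajectories[[i]])
    tibble::tibble(saccade = i, time = df$time,
                   x = df$x_true_1, y = df$x_true_2)
  })
  targets <- tibble::tibble(x = object$world$quadrant_centers[, 1L],
                            y = object$world$quadrant_centers[, 2L])
  ggplot2::ggplot(paths, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(colour = factor(.data$saccade)),
                       show.legend = FALSE) +
    ggplot2::geom_point(data = targets, shape = 3, size = 4, colour = "red") +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "gaze x", y = "gaze y",
                  title = "Saccadic sampling of the pictogram array") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
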
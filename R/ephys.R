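#' Zero-phase band-pass filtering of firing-rate rasters
#'
#' Applies a Butterworth band-pass (default 4-32 Hz, 4th order) forwards
#' and backwards ([signal::filtfilt()], zero phase) to each unit's firing
#' rate, yielding traces that can be read as band-passed fluctuations in
#' depolarization (simulated local field potentials). Records shorter than
#' the filter warm-up are edge-padded with a warning.
#'
#' @param raster Matrix `units x bins` of firing rates in `[0, 1]`.
#' @param bin_ms Bin width in milliseconds.
#' @param band_hz Pass band (Hz), default `c(4, 32)`.
#' @param order Butterworth order (default 4).
#' @return Matrix of the same shape (the LFP traces).
#' @export
bandpass_lfp <- function(raster, bin_ms, band_hz = c(4, 32), order = 4L) {
  fs <- 1000 / bin_ms
  if (band_hz[2L] >= fs / 2) stopf("bandpass_lfp: band edge above Nyquist (%.3g Hz)", fs / 2)
  bf <- signal::butter(order, band_hz / (fs / 2), type = "pass")
  n <- ncol(raster)
  warmup <- 3L * (2L * order + 1L)
  if (n < warmup) {
    warnf("bandpass_lfp: record (%d bins) shorter than filter warm-up (%d); edge-padded",
          n, warmup)
  }
  # odd-reflection padding at both ends so boundary steps are filtered like
  # interior ones (filtfilt itself applies no padding)
  npad <- min(n - 1L, as.integer(ceiling(3 * fs / band_hz[1L])))
  t(apply(raster, 1L, function(x) {
    x <- x - mean(x)
    head_pad <- 2 * x[1L] - x[seq(npad + 1L, 2L)]
    tail_pad <- 2 * x[n] - x[seq(n - 1L, n - npad)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[npad + seq_len(n)]
  }))
}

#' Simulated electrophysiology from a nested reading trial
#'
#' Assembles firing-rate rasters from the per-iteration Bayesian model
#' averages of both discrete levels on a common timeline (one bin per
#' gradient iteration or continuous integration step), band-passes them
#' into simulated local field potentials, and marks saccade onsets.
#' Sentence units are sustained while the lower level gathers information
#' with a saccade or two; word units fluctuate quickly with each visual
#' sample.
#'
#' @param deep A `bp_deep_trial` from [run_deep()] with
#'   `record_iterations = TRUE`.
#' @param bin_ms Bin width (ms); the default timing uses 256/24 ms so that
#'   a 24-step saccade lasts 256 ms.
#' @param band_hz,order Band-pass parameters (see [bandpass_lfp()]).
#' @param steps_per_saccade Continuous window length in bins.
#' @return A `bp_ephys` object: `raster` (`units x bins` in `[0, 1]`),
#'   `lfp` (same shape), `time_s`, `saccade_onsets_s`, `unit_labels` and
#'   `unit_level`.
#' @export
simulate_ephys <- function(deep, bin_ms = 256 / 24, band_hz = c(4, 32),
                           order = 4L, steps_per_saccade = 24L) {
  if (is.null(deep$iter_bma)) stopf("simulate_ephys: run_deep must record iterations")
  hi <- deep$model
  lo <- deep$lower[[1L]]$model
  n_hi <- hi$n_states[1L]
  n_lo <- lo$n_states[1L]

  hi_state <- rep(1 / n_hi, n_hi)
  lo_state <- rep(1 / n_lo, n_lo)
  cols_hi <- list(); cols_lo <- list()
  onsets <- integer(0)
  bin <- 0L

  push <- function(k) {
    cols_hi[[length(cols_hi) + 1L]] <<- matrix(hi_state, n_hi, k)
    cols_lo[[length(cols_lo) + 1L]] <<- matrix(lo_state, n_lo, k)
    bin <<- bin + k
  }

  for (t in seq_len(deep$T)) {
    lower <- deep$lower[[t]]
    lo_state <- rep(1 / n_lo, n_lo)   # new word: fresh lower-level units
    for (e in seq_len(lower$T)) {
      onsets <- c(onsets, bin + 1L)
      push(steps_per_saccade)          # continuous window: beliefs sustained
      for (it_bma in lower$iter_bma[[e]]) {
        lo_state <- factor_marginal(it_bma[, 1L], lo$n_states, 1L)
        push(1L)
      }
    }
    for (it_bma in deep$iter_bma[[t]]) {
      hi_state <- factor_marginal(it_bma[, 1L], hi$n_states, 1L)
      push(1L)
    }
  }

  raster <- rbind(do.call(cbind, cols_hi), do.call(cbind, cols_lo))
  labels <- c(paste0("sentence_", seq_len(n_hi)), paste0("word_", seq_len(n_lo)))
  lfp <- bandpass_lfp(raster, bin_ms, band_hz, order)

  structure(list(
    raster = raster, lfp = lfp,
    time_s = seq_len(ncol(raster)) * bin_ms / 1000,
    saccade_onsets_s = onsets * bin_ms / 1000,
    unit_labels = labels,
    unit_level = rep(c(2L, 1L), c(n_hi, n_lo)),
    bin_ms = bin_ms, band_hz = band_hz
  ), class = "bp_ephys")
}

#' @export
print.bp_ephys <- function(x, ...) {
  cat(sprintf("<bp_ephys: %d unit(s) x %d bin(s) (%.2f s), band %g-%g Hz, %d saccade(s)>\n",
              nrow(x$raster), ncol(x$raster), max(x$time_s),
              x$band_hz[1L], x$band_hz[2L], length(x$saccade_onsets_s)))
  invisible(x)
}

#' Fraction of spectral power inside a frequency band
#'
#' Hann-tapered periodogram estimate of the share of (non-DC) spectral
#' power inside a band; the taper avoids rectangular-window leakage from
#' transient-rich records.
#'
#' @param trace Numeric vector (one LFP trace).
#' @param bin_ms Bin width (ms).
#' @param band_hz Frequency band.
#' @return Fraction of non-DC spectral power inside the band.
#' @export
band_power_fraction <- function(trace, bin_ms, band_hz = c(4, 32)) {
  n <- length(trace)
  fs <- 1000 / bin_ms
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  sp <- Mod(stats::fft((trace - mean(trace)) * taper))^2
  freq <- (seq_len(n) - 1L) * fs / n
  half <- freq <= fs / 2 & freq > 0
  inband <- half & freq >= band_hz[1L] & freq <= band_hz[2L]
  sum(sp[inband]) / sum(sp[half])
}
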
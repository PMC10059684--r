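#' Continuous multichannel recording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channels unique channel labels.
#' @param eog_channels labels of ocular channels (excluded from the average
#'   reference, used for trial rejection).
#' @param events data.frame with columns `onset_sample` and `code` (optional).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, channels, eog_channels = character(0),
                          events = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  if (nrow(data) != length(channels)) .stopf("channel labels do not match data")
  if (anyDuplicated(channels)) .stopf("channel labels must be unique")
  if (!all(eog_channels %in% channels)) .stopf("eog_channels must be in channels")
  structure(list(data = data, fs = fs, channels = channels,
                 eog_channels = eog_channels,
                 events = events, log = character(0)),
            class = "raw_recording")
}

#' @export
#' @method print raw_recording
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

# ---- FIR design (windowed sinc, Hamming). No DSP package is available in
# this environment, so the designs are written out; kernels are symmetric
# (exactly linear phase) and applied with delay compensation, i.e. zero-phase.

.fir_lowpass <- function(n_taps, fc, fs) {
  stopifnot(n_taps %% 2 == 1)
  m <- (n_taps - 1) / 2
  k <- -m:m
  h <- 2 * fc / fs * sinc(2 * fc / fs * k)
  w <- 0.54 + 0.46 * cos(pi * k / m) # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

.fir_highpass <- function(n_taps, fc, fs) {
  h <- -.fir_lowpass(n_taps, fc, fs) # spectral inversion
  m <- (n_taps - 1) / 2
  h[m + 1] <- h[m + 1] + 1
  h
}

.fir_bandstop <- function(n_taps, f_lo, f_hi, fs) {
  .fir_lowpass(n_taps, f_lo, fs) + .fir_highpass(n_taps, f_hi, fs)
}

# Zero-phase FIR filtering of each row, edge-padded by reflection.
.filt_rows <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- ncol(x)
  pad_l <- x[, pmin(m, n):1, drop = FALSE]
  if (m > n) pad_l <- cbind(matrix(x[, 1], nrow(x), m - n), pad_l)
  pad_r <- x[, n:pmax(1, n - m + 1), drop = FALSE]
  if (m > n) pad_r <- cbind(pad_r, matrix(x[, n], nrow(x), m - n))
  xp <- cbind(pad_l, x, pad_r)
  out <- t(apply(xp, 1, function(r) stats::convolve(r, rev(h), type = "filter")))
  out[, seq_len(n) + (ncol(out) - n) / 2, drop = FALSE]
}

#' Preprocess a continuous recording
#'
#' Applies the standard chain: anti-aliased down-sampling to `fs_target`
#' (integer decimation), a zero-phase FIR high-pass (> `hp_cutoff`), a
#' zero-phase FIR band-stop over `notch_band`, and an average reference over
#' the EEG channels (EOG excluded). Zero-phase filtering matters here because
#' spatial phase gradients are the downstream measurement; a causal filter's
#' group delay would bias wave direction estimates. Each step is logged on
#' the returned object.
#'
#' @param raw a [raw_recording()].
#' @param fs_target output sampling rate; `fs/fs_target` must be an integer.
#' @param hp_cutoff high-pass cutoff (Hz).
#' @param notch_band length-2 band-stop interval (Hz), e.g. `c(47, 53)` for
#'   50-Hz mains.
#' @return The filtered, re-referenced `raw_recording` at `fs_target`, with
#'   event sample indices rescaled.
#' @export
preprocess <- function(raw, fs_target = 256, hp_cutoff = 1,
                       notch_band = c(47, 53)) {
  stopifnot(inherits(raw, "raw_recording"))
  if (fs_target > raw$fs) .stopf("fs_target (%g) exceeds fs (%g)", fs_target, raw$fs)
  if (max(hp_cutoff, notch_band) >= fs_target / 2)
    .stopf("filter cutoffs must lie below fs_target/2")
  x <- raw$data
  fs <- raw$fs
  logs <- raw$log
  dec <- fs / fs_target
  if (abs(dec - round(dec)) > 1e-9)
    .stopf("fs/fs_target must be an integer decimation factor (got %g)", dec)
  dec <- round(dec)
  if (dec > 1) {
    n_aa <- 2 * ceiling(3.3 * fs / (0.2 * fs_target)) + 1
    x <- .filt_rows(x, .fir_lowpass(n_aa, 0.4 * fs_target, fs))
    x <- x[, seq(1, ncol(x), by = dec), drop = FALSE]
    fs <- fs_target
    logs <- c(logs, sprintf("decimated x%d to %g Hz (FIR anti-alias, %d taps)",
                            dec, fs, n_aa))
  }
  n_hp <- 2 * ceiling(3.3 * fs / hp_cutoff / 2) * 2 + 1
  n_hp <- min(n_hp, 2 * floor((ncol(x) - 1) / 2) + 1)
  x <- .filt_rows(x, .fir_highpass(n_hp, hp_cutoff, fs))
  logs <- c(logs, sprintf("high-pass > %g Hz (zero-phase FIR, %d taps)", hp_cutoff, n_hp))
  n_bs <- 2 * ceiling(1.5 * fs) %/% 2 * 2 + 1
  n_bs <- min(n_bs, 2 * floor((ncol(x) - 1) / 2) + 1)
  x <- .filt_rows(x, .fir_bandstop(n_bs, notch_band[1], notch_band[2], fs))
  logs <- c(logs, sprintf("band-stop %g-%g Hz (zero-phase FIR, %d taps)",
                          notch_band[1], notch_band[2], n_bs))
  eeg <- !(raw$channels %in% raw$eog_channels)
  x[eeg, ] <- sweep(x[eeg, , drop = FALSE], 2, colMeans(x[eeg, , drop = FALSE]))
  logs <- c(logs, "average reference over EEG channels (EOG excluded)")
  ev <- raw$events
  if (!is.null(ev) && dec > 1)
    ev$onset_sample <- floor((ev$onset_sample - 1) / dec) + 1
  out <- raw_recording(x, fs, raw$channels, raw$eog_channels, ev)
  out$log <- logs
  out
}

#' Apply (or re-apply) the average reference
#' @param raw a [raw_recording()].
#' @export
average_reference <- function(raw) {
  eeg <- !(raw$channels %in% raw$eog_channels)
  raw$data[eeg, ] <- sweep(raw$data[eeg, , drop = FALSE], 2,
                           colMeans(raw$data[eeg, , drop = FALSE]))
  raw
}

#' Cut a continuous recording into trial epochs
#'
#' No filtering happens here: concatenating the extracted (non-overlapping)
#' epochs reproduces the raw segments exactly. Sample t = 0 is aligned to each
#' onset.
#'
#' @param raw a [raw_recording()].
#' @param trial_onsets 1-based onset sample indices.
#' @param t_start,t_end epoch window in seconds relative to onset (default
#'   -0.5 to 5, i.e. 500 ms of pre-trial baseline).
#' @param metadata optional per-trial metadata data.frame.
#' @return An [epoch_set()].
#' @export
epoch <- function(raw, trial_onsets, t_start = -0.5, t_end = 5, metadata = NULL) {
  stopifnot(inherits(raw, "raw_recording"), t_end > t_start)
  fs <- raw$fs
  n <- ncol(raw$data)
  i0 <- trial_onsets + round(t_start * fs)
  i1 <- i0 + round((t_end - t_start) * fs) - 1
  bad <- which(i0 < 1 | i1 > n)
  if (length(bad))
    .stopf("epoch window out of bounds for trial(s): %s",
           paste(bad, collapse = ", "))
  n_samp <- round((t_end - t_start) * fs)
  dat <- array(0, c(length(trial_onsets), nrow(raw$data), n_samp))
  for (k in seq_along(trial_onsets)) dat[k, , ] <- raw$data[, i0[k]:i1[k]]
  if (is.null(metadata))
    metadata <- data.frame(trial = seq_along(trial_onsets))
  epoch_set(dat, fs, raw$channels, metadata, t_start, raw$eog_channels)
}

#' Reject trials with ocular artifacts
#'
#' A trial is removed when any EOG channel exceeds `threshold_uv` peak-to-peak
#' or shows a step larger than `step_uv` between the means of adjacent 100-ms
#' windows (a saccade signature). The thresholds follow common EEG practice
#' and are exposed as arguments.
#'
#' @param epochs an [epoch_set()] containing EOG channels.
#' @param eog_labels channels to screen (default: the set's `eog_channels`).
#' @param threshold_uv peak-to-peak rejection threshold.
#' @param step_uv sliding-mean step threshold.
#' @return The pruned `epoch_set`; removed trial indices and count are in
#'   attributes `rejected` and `n_rejected`.
#' @export
reject_eog_trials <- function(epochs, eog_labels = epochs$eog_channels,
                              threshold_uv = 100, step_uv = 50) {
  if (length(eog_labels) == 0) .stopf("no EOG channels available for rejection")
  idx <- match(eog_labels, epochs$channels)
  if (anyNA(idx)) .stopf("EOG channel(s) not found: %s",
                         paste(eog_labels[is.na(idx)], collapse = ", "))
  w <- max(1, round(0.1 * epochs$fs))
  bad <- vapply(seq_len(n_trials(epochs)), function(tr) {
    for (ch in idx) {
      x <- epochs$data[tr, ch, ]
      if (diff(range(x)) > threshold_uv) return(TRUE)
      if (length(x) >= 2 * w) {
        cs <- cumsum(x)
        means <- (cs[w:length(x)] - c(0, cs)[1:(length(x) - w + 1)]) / w
        if (length(means) > w &&
            max(abs(means[(w + 1):length(means)] -
                    means[1:(length(means) - w)])) > step_uv)
          return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  out <- epochs[!bad]
  attr(out, "rejected") <- which(bad)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Simulate a continuous recording (for preprocessing tests)
#'
#' Concatenates inter-trial background and simulated trials into one
#' continuous multichannel signal with an event table, at an acquisition rate
#' that is an integer multiple of the analysis rate.
#'
#' @param config a [sim_config()]; `fs` here is the acquisition rate.
#' @param n_trials number of trials to lay out.
#' @param gap_s inter-trial gap in seconds.
#' @param seed integer seed.
#' @return A [raw_recording()] with `events` rows at each trial onset.
#' @export
simulate_raw_recording <- function(config = sim_config(), n_trials = 4,
                                   gap_s = 1, seed = config$seed) {
  fs <- config$fs
  n_trial <- round(config$trial_duration * fs)
  n_gap <- round(gap_s * fs)
  chans <- c(biosemi64_labels(), "EXG1", "EXG2", "EXG3")
  .with_seed(seed, {
    total <- n_gap + n_trials * (n_trial + n_gap)
    x <- generate_background(length(chans), total, fs,
                             config$one_over_f_exponent, config$noise_amplitude)
    onsets <- n_gap + (seq_len(n_trials) - 1) * (n_trial + n_gap) + 1
    mid <- match(line_electrodes(default_line_set(), "mid"), chans)
    for (k in seq_along(onsets)) {
      seg <- onsets[k]:(onsets[k] + n_trial - 1)
      cmp <- wave_component(10, config$alpha_amp, config$phase_step,
                            phase = stats::runif(1, 0, 2 * pi))
      x[, seg] <- inject_wave(x[, seg, drop = FALSE], mid, cmp, fs)
    }
    raw_recording(x, fs, chans, c("EXG1", "EXG2", "EXG3"),
                  events = data.frame(onset_sample = onsets, code = "trial"))
  })
}
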
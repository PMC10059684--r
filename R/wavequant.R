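#' Frequency-band definitions
#'
#' Defaults: theta 4-7 Hz, alpha 8-12 Hz, low beta 13-24 Hz, high beta/gamma
#' 25-45 Hz. A band averages the FFT bins whose center frequency lies in
#' `[f_lo, f_hi]`; on the default 500-ms window the grid spacing is 2 Hz, so
#' alpha averages the 8, 10 and 12 Hz bins.
#'
#' @return data.frame with columns `band`, `f_lo`, `f_hi`.
#' @export
default_bands <- function() {
  data.frame(band = c("theta", "alpha", "low_beta", "high_beta_gamma"),
             f_lo = c(4, 8, 13, 25), f_hi = c(7, 12, 24, 45),
             stringsAsFactors = FALSE)
}

# Spatial DFT matrix with exact conjugate symmetry: entry [k, e] =
# w[(k-1)(e-1) mod n] with w[n - j] == Conj(w[j]) bit-for-bit by
# construction. This makes electrode-reversal equivalences exact in floating
# point, which the directional analysis exploits (see fft2d_directional).
.spatial_dft_matrix <- function(n) {
  w <- complex(length.out = n)
  w[1] <- 1 + 0i
  for (j in seq_len(floor(n / 2))) w[j + 1] <- exp(-2i * pi * j / n)
  if (n %% 2 == 0) w[n / 2 + 1] <- complex(real = -1, imaginary = 0)
  for (j in seq_len(ceiling(n / 2) - 1)) w[n - j + 1] <- Conj(w[j + 1])
  idx <- outer(0:(n - 1), 0:(n - 1)) %% n
  matrix(w[idx + 1], n, n)
}

# Quadrant row indices for an n-electrode spatial DFT: 'neg' rows carry
# negative spatial frequencies (forward waves at positive temporal
# frequency), 'pos' rows positive ones. Row 1 (k_s = 0, standing) and the
# Nyquist row for even n are excluded.
.quadrant_rows <- function(n) {
  half <- floor((n - 1) / 2)
  list(pos = 2:(1 + half), neg = (n - half + 1):n)
}

#' Sliding space-time windows over one trial and line
#'
#' @param map `n_electrodes x n_samples` matrix, rows ordered occipital to
#'   frontal.
#' @param fs sampling rate (Hz).
#' @param win_s,overlap_s window length and overlap in seconds (defaults
#'   500 ms / 250 ms: a 5-s trial at 256 Hz yields 19 windows of 128 samples).
#' @return list of `n_electrodes x win` matrices.
#' @export
extract_windows <- function(map, fs, win_s = 0.5, overlap_s = 0.25) {
  if (overlap_s >= win_s) .stopf("overlap_s must be smaller than win_s")
  win <- round(win_s * fs)
  hop <- win - round(overlap_s * fs)
  if (ncol(map) < win) .stopf("signal shorter than one window")
  starts <- seq(1, ncol(map) - win + 1, by = hop)
  lapply(starts, function(s) map[, s:(s + win - 1), drop = FALSE])
}

#' Directional 2D-FFT spectrum of a space-time map
#'
#' Computes the 2D discrete Fourier transform of the electrode x time map and
#' reduces it to two 1D spectra: for each temporal frequency bin in `f_range`,
#' `fw_raw` is the maximum power (squared magnitude) over spatial frequencies
#' in the forward quadrant and `bw_raw` the maximum in the conjugate
#' quadrant. With rows
#' ordered occipital to frontal, a forward wave (phase increasing toward
#' frontal) concentrates energy where temporal and spatial frequency indices
#' have opposite signs; that quadrant is `fw`. The `k_s = 0` line (standing
#' oscillations, directionless) is excluded from the maxima.
#'
#' The backward quadrant is evaluated as the forward computation applied to
#' the electrode-reversed map - the same quantity in exact arithmetic - so
#' reversing the electrode order swaps `fw_raw` and `bw_raw` bit-for-bit.
#'
#' @param map `n_electrodes x n_samples` matrix (>= 2 electrodes, >= 4
#'   samples), occipital row first.
#' @param fs sampling rate in Hz.
#' @param f_range temporal frequency range to keep (default 2-45 Hz).
#' @return data.frame with `freq`, `fw_raw`, `bw_raw`.
#' @export
fft2d_directional <- function(map, fs, f_range = c(2, 45)) {
  if (anyNA(map) || !all(is.finite(map))) .stopf("map contains NA/non-finite values")
  n_e <- nrow(map); W <- ncol(map)
  if (n_e < 2 || W < 4) .stopf("need >= 2 electrodes and >= 4 samples")
  Tfft <- t(stats::mvfft(t(map)))
  sel <- .bin_select(W, fs, f_range)
  Ts <- Tfft[, sel$idx, drop = FALSE]
  Wn <- .spatial_dft_matrix(n_e)
  q <- .quadrant_rows(n_e)
  fw <- .colmax_rows(Mod(Wn %*% Ts)^2, q$neg)
  bw <- .colmax_rows(Mod(Wn %*% Ts[n_e:1, , drop = FALSE])^2, q$neg)
  data.frame(freq = sel$freq, fw_raw = fw, bw_raw = bw)
}

# Positive-frequency DFT bins of a W-sample window inside f_range.
.bin_select <- function(W, fs, f_range) {
  freqs <- (seq_len(W) - 1) * fs / W
  idx <- which(freqs >= f_range[1] & freqs <= min(f_range[2], fs / 2))
  if (length(idx) == 0) .stopf("no frequency bins inside [%g, %g] Hz",
                               f_range[1], f_range[2])
  list(idx = idx, freq = freqs[idx])
}

#' Electrode-shuffled surrogate baseline
#'
#' Repeats the directional analysis after uniformly permuting the electrode
#' rows and averages the quadrant maxima over shuffles. Per-electrode temporal
#' spectra are untouched by construction, so the surrogate keeps the 1/f trend
#' and any standing peaks but destroys spatial phase order. The identity
#' permutation is allowed (probability 1/n! under uniform sampling). Shuffles
#' are aggregated by their geometric mean, which makes the downstream dB
#' statistic exactly unbiased under the null (the raw maximum is exchangeable
#' with every shuffle maximum, so the expected log ratio is zero).
#'
#' With `exhaustive = TRUE` all `n_electrodes!` permutations are enumerated
#' and averaged by sorted summation; forward and backward assignments are
#' exchangeable under the permutation group, so `fw_ss` and `bw_ss` are then
#' exactly equal.
#'
#' @inheritParams fft2d_directional
#' @param n_shuffles number of random permutations (default 100; the source
#'   procedure does not state a count).
#' @param exhaustive enumerate all permutations instead of sampling.
#' @param seed optional seed for the shuffle draw.
#' @return data.frame with `freq`, `fw_ss`, `bw_ss`.
#' @export
surrogate_baseline <- function(map, fs, f_range = c(2, 45), n_shuffles = 100,
                               exhaustive = FALSE, seed = NULL) {
  if (!exhaustive && (!.is_count(n_shuffles)))
    .stopf("n_shuffles must be a positive count")
  n_e <- nrow(map); W <- ncol(map)
  Tfft <- t(stats::mvfft(t(map)))
  sel <- .bin_select(W, fs, f_range)
  Ts <- Tfft[, sel$idx, drop = FALSE]
  Wn <- .spatial_dft_matrix(n_e)
  q <- .quadrant_rows(n_e)
  perms <- if (exhaustive) .all_perms(n_e) else
    .with_seed(seed, t(replicate(n_shuffles, sample.int(n_e))))
  S <- nrow(perms)
  fw <- matrix(0, S, length(sel$idx))
  bw <- matrix(0, S, length(sel$idx))
  for (s in seq_len(S)) {
    p <- perms[s, ]
    fw[s, ] <- .colmax_rows(Mod(Wn %*% Ts[p, , drop = FALSE])^2, q$neg)
    bw[s, ] <- .colmax_rows(Mod(Wn %*% Ts[rev(p), , drop = FALSE])^2, q$neg)
  }
  # geometric mean across shuffles: the dB statistic then has expectation
  # exactly zero under electrode exchangeability (the raw maximum and each
  # shuffle maximum are identically distributed, and the log-average cancels),
  # which keeps white-noise spectra centered on 0 dB
  if (exhaustive) {
    # sorted summation: the fw and bw value multisets are bit-identical
    # (reversal is a bijection on the permutation group), so the means agree
    # exactly
    fw_ss <- apply(fw, 2, function(v) exp(mean(sort(log(v)))))
    bw_ss <- apply(bw, 2, function(v) exp(mean(sort(log(v)))))
  } else {
    fw_ss <- exp(colMeans(log(fw)))
    bw_ss <- exp(colMeans(log(bw)))
  }
  data.frame(freq = sel$freq, fw_ss = fw_ss, bw_ss = bw_ss)
}

.perm_cache <- new.env(parent = emptyenv())
.all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], rec(v[-i]))))
  }
  p <- rec(seq_len(n))
  .perm_cache[[key]] <- p
  p
}

#' Wave amount in decibels
#'
#' `10 * log10(raw / surrogate)`: 0 dB means no difference from the
#' electrode-shuffled null, +3.0103 dB a doubling.
#'
#' @param raw,surrogate quadrant maxima (surrogate must be > 0).
#' @export
waves_db <- function(raw, surrogate) {
  if (any(!is.finite(surrogate)) || any(surrogate <= 0))
    .stopf("surrogate values must be positive")
  10 * log10(raw / surrogate)
}

# ---- batched engine -------------------------------------------------------
# Computes window-wise FW/BW dB for every trial of one line in a few large
# matrix operations: one temporal FFT over all stacked windows, then a single
# complex matrix product whose left factor stacks the spatial DFT matrix
# under the identity and all sampled electrode permutations (and their
# reversals, which give the backward quadrant). dB is computed per window and
# averaged across windows within each trial.
#
# arr: n_trials x n_e x n_samples; returns list(freq, fw_db, bw_db) with
# matrices n_trials x n_bins.
.line_wave_db <- function(arr, fs, win_s = 0.5, overlap_s = 0.25,
                          f_range = c(2, 45), n_shuffles = 100, seed = NULL,
                          chunk_cells = 2.5e7) {
  n_tr <- dim(arr)[1]; n_e <- dim(arr)[2]; n_samp <- dim(arr)[3]
  win <- round(win_s * fs)
  hop <- win - round(overlap_s * fs)
  if (hop <= 0) .stopf("overlap_s must be smaller than win_s")
  starts <- seq(1, n_samp - win + 1, by = hop)
  n_w <- length(starts)
  sel <- .bin_select(win, fs, f_range)
  nb <- length(sel$idx)
  Wn <- .spatial_dft_matrix(n_e)
  q <- .quadrant_rows(n_e)
  S <- n_shuffles
  perms <- .with_seed(seed, t(replicate(S, sample.int(n_e))))
  # row blocks: 1 = real FW, 2 = real BW, then alternating shuffle FW/BW
  blocks <- vector("list", 2 + 2 * S)
  blocks[[1]] <- Wn[, order(seq_len(n_e))]
  blocks[[2]] <- Wn[, order(rev(seq_len(n_e)))]
  for (s in seq_len(S)) {
    blocks[[2 * s + 1]] <- Wn[, order(perms[s, ])]
    blocks[[2 * s + 2]] <- Wn[, order(rev(perms[s, ]))]
  }
  Wbig <- do.call(rbind, blocks)
  n_blk <- 2 + 2 * S
  idxmat <- outer(0:(win - 1), starts, "+") # win x n_w sample indices

  fw_db <- matrix(0, n_tr, nb)
  bw_db <- matrix(0, n_tr, nb)
  cells_per_trial <- n_blk * n_e * nb * n_w
  chunk <- max(1L, floor(chunk_cells / cells_per_trial))
  for (lo in seq(1, n_tr, by = chunk)) {
    trs <- lo:min(lo + chunk - 1, n_tr)
    # windows of all trials stacked: win x (n_e * n_w * n_trials_chunk)
    M <- vapply(trs, function(tr) {
      sub <- matrix(arr[tr, , ], n_e, n_samp)
      aperm(array(sub[, c(idxmat)], c(n_e, win, n_w)), c(2, 1, 3))
    }, array(0, c(win, n_e, n_w)))
    dim(M) <- c(win, n_e * n_w * length(trs))
    Tf <- stats::mvfft(M)[sel$idx, , drop = FALSE] # nb x (n_e*n_w*ntr)
    Tm <- array(Tf, c(nb, n_e, n_w * length(trs)))
    Tm <- matrix(aperm(Tm, c(2, 1, 3)), n_e) # n_e x (nb*n_w*ntr)
    A <- Mod(Wbig %*% Tm)^2 # power; (n_blk*n_e) x (nb*n_w*ntr)
    dim(A) <- c(n_e, n_blk, nb * n_w * length(trs))
    mx <- Reduce(pmax, lapply(q$neg, function(r) A[r, , ])) # n_blk x cols
    dim(mx) <- c(n_blk, nb, n_w, length(trs))
    fw_raw <- mx[1, , , , drop = FALSE]
    bw_raw <- mx[2, , , , drop = FALSE]
    sh_f <- mx[seq(3, n_blk, by = 2), , , , drop = FALSE]
    sh_b <- mx[seq(4, n_blk, by = 2), , , , drop = FALSE]
    # geometric surrogate mean: dB is exactly null-calibrated (see
    # surrogate_baseline)
    fw_ss <- colMeans(log10(array(sh_f, c(S, nb * n_w * length(trs)))))
    bw_ss <- colMeans(log10(array(sh_b, c(S, nb * n_w * length(trs)))))
    dbf <- 10 * (log10(as.vector(fw_raw)) - fw_ss)
    dbb <- 10 * (log10(as.vector(bw_raw)) - bw_ss)
    dim(dbf) <- c(nb, n_w, length(trs)); dim(dbb) <- dim(dbf)
    # average dB across windows within each trial
    fw_db[trs, ] <- t(colMeans(aperm(dbf, c(2, 1, 3))))
    bw_db[trs, ] <- t(colMeans(aperm(dbb, c(2, 1, 3))))
  }
  list(freq = sel$freq, fw_db = fw_db, bw_db = bw_db)
}

#' Directional wave spectrum of single trials along one line
#'
#' Slides 500-ms windows (250-ms overlap) over the trial, computes the
#' surrogate-referenced forward/backward amplitude in dB per window, and
#' averages dB across windows.
#'
#' @param epochs an [epoch_set()].
#' @param line character vector of 7 electrode labels (occipital to frontal)
#'   or a line id resolvable in `lines`.
#' @param lines optional [line_set()] used to resolve `line`.
#' @param trials trial indices (default all).
#' @param f_range temporal frequency range (Hz).
#' @param n_shuffles surrogate permutations per window.
#' @param win_s,overlap_s window geometry in seconds.
#' @param seed seed for the shuffle draw.
#' @return data.frame `trial`, `freq`, `fw_db`, `bw_db`.
#' @export
trial_wave_spectrum <- function(epochs, line, lines = NULL, trials = NULL,
                                f_range = c(2, 45), n_shuffles = 100,
                                win_s = 0.5, overlap_s = 0.25, seed = NULL) {
  labels <- if (length(line) == 1 && !is.null(lines))
    line_electrodes(lines, line) else line
  arr <- .line_array(epochs, labels)
  if (is.null(trials)) trials <- seq_len(dim(arr)[1])
  arr <- arr[trials, , , drop = FALSE]
  res <- .line_wave_db(arr, epochs$fs, win_s, overlap_s, f_range, n_shuffles,
                       seed = seed)
  data.frame(trial = rep(epochs$metadata$trial[trials], length(res$freq)),
             freq = rep(res$freq, each = length(trials)),
             fw_db = as.vector(res$fw_db), bw_db = as.vector(res$bw_db))
}

#' Wave spectra for every line of a line set
#'
#' @inheritParams trial_wave_spectrum
#' @param lines a [line_set()].
#' @return Long data.frame `subject`, `trial`, `line_id`, `freq`, `fw_db`,
#'   `bw_db`.
#' @export
wave_spectra <- function(epochs, lines, trials = NULL, f_range = c(2, 45),
                         n_shuffles = 100, win_s = 0.5, overlap_s = 0.25,
                         seed = NULL) {
  if (is.null(trials)) trials <- seq_len(n_trials(epochs))
  out <- lapply(seq_len(nrow(lines)), function(i) {
    sp <- trial_wave_spectrum(epochs, lines$line_id[i], lines, trials,
                              f_range, n_shuffles, win_s, overlap_s,
                              seed = if (is.null(seed)) NULL else seed + i)
    sp$line_id <- lines$line_id[i]
    sp
  })
  out <- do.call(rbind, out)
  md <- epochs$metadata
  out$subject <- md$subject[match(out$trial, md$trial)]
  out
}

#' Band-averaged wave table
#'
#' Averages trial spectra into the unit of all downstream statistics: one dB
#' value per subject, line, laterality, direction and frequency band. dB is
#' first averaged over trials, then over the FFT bins whose center lies in
#' the band. Laterality is assigned per trial from the attended side and the
#' line's hemisphere (a left line on an attend-right trial is contralateral).
#'
#' @param spectra long spectra from [wave_spectra()].
#' @param metadata the epoch metadata (needs `trial`, `subject`,
#'   `attended_side`).
#' @param lines the [line_set()] used.
#' @param bands band definition data.frame (see [default_bands()]).
#' @return data.frame `subject`, `pair_id` (`"mid"` for the midline),
#'   `laterality`, `direction`, `band`, `value_db`. Lateral homologues are
#'   pooled by pair: the contralateral value of pair i combines the left line
#'   on attend-right trials with the right line on attend-left trials, giving
#'   the five contralateral and five ipsilateral values per subject and
#'   direction that enter the statistics.
#' @export
band_table <- function(spectra, metadata, lines, bands = default_bands()) {
  md <- metadata
  key <- paste(md$subject, md$trial)
  skey <- paste(spectra$subject, spectra$trial)
  side <- md$attended_side[match(skey, key)]
  li <- match(spectra$line_id, lines$line_id)
  spectra$laterality <- .laterality(lines$hemisphere[li], side)
  spectra$pair_id <- ifelse(spectra$laterality == "mid", "mid",
                            lines$pair_id[li])
  for (b in seq_len(nrow(bands))) {
    inb <- spectra$freq >= bands$f_lo[b] & spectra$freq <= bands$f_hi[b]
    if (!any(inb)) .stopf("band '%s' contains no frequency bins", bands$band[b])
  }
  long <- rbind(
    data.frame(spectra[c("subject", "pair_id", "laterality", "freq")],
               direction = "FW", db = spectra$fw_db),
    data.frame(spectra[c("subject", "pair_id", "laterality", "freq")],
               direction = "BW", db = spectra$bw_db))
  # trial average first, then band average over bins
  per_freq <- stats::aggregate(db ~ subject + pair_id + laterality + direction + freq,
                               long, mean)
  out <- NULL
  for (b in seq_len(nrow(bands))) {
    inb <- per_freq$freq >= bands$f_lo[b] & per_freq$freq <= bands$f_hi[b]
    agg <- stats::aggregate(db ~ subject + pair_id + laterality + direction,
                            per_freq[inb, ], mean)
    agg$band <- bands$band[b]
    out <- rbind(out, agg)
  }
  names(out)[names(out) == "db"] <- "value_db"
  out[order(out$subject, out$band, out$direction, out$pair_id), ]
}

#' Normalize homologous line pairs
#'
#' Within each (subject, pair, band, direction), subtracts the mean of the
#' contralateral and ipsilateral values, removing per-line power offsets so
#' hemispheres can be compared: `normalized_db = value_db - (contra + ipsi)/2`.
#' The two normalized values of a pair sum to zero. The midline is left
#' unnormalized (`normalized_db = NA`) and takes no part in laterality
#' contrasts.
#'
#' @param tbl a [band_table()].
#' @return `tbl` with a `normalized_db` column.
#' @export
normalize_pairs <- function(tbl) {
  tbl$normalized_db <- NA_real_
  lat <- which(tbl$laterality != "mid")
  key <- paste(tbl$subject, tbl$pair_id, tbl$band, tbl$direction)[lat]
  for (k in unique(key)) {
    i <- lat[key == k]
    if (length(i) != 2 || !setequal(tbl$laterality[i], c("contra", "ipsi")))
      .stopf("incomplete pair for '%s'", k)
    tbl$normalized_db[i] <- tbl$value_db[i] - mean(tbl$value_db[i])
  }
  tbl
}

#' Per-trial band-averaged wave values
#'
#' Averages each trial's spectrum over the bins of one band, then over the
#' lines of each laterality; used for trial-by-trial wave-power correlation.
#'
#' @inheritParams band_table
#' @param band length-2 numeric band (Hz), default alpha 8-12.
#' @return data.frame `subject`, `trial`, `laterality`, `direction`,
#'   `alpha_db`.
#' @export
trial_band_waves <- function(spectra, metadata, lines, band = c(8, 12)) {
  md <- metadata
  key <- paste(md$subject, md$trial)
  side <- md$attended_side[match(paste(spectra$subject, spectra$trial), key)]
  hemi <- lines$hemisphere[match(spectra$line_id, lines$line_id)]
  spectra$laterality <- .laterality(hemi, side)
  sp <- spectra[spectra$freq >= band[1] & spectra$freq <= band[2] &
                  spectra$laterality != "mid", ]
  long <- rbind(
    data.frame(sp[c("subject", "trial", "laterality")], direction = "FW",
               db = sp$fw_db),
    data.frame(sp[c("subject", "trial", "laterality")], direction = "BW",
               db = sp$bw_db))
  out <- stats::aggregate(db ~ subject + trial + laterality + direction, long, mean)
  names(out)[names(out) == "db"] <- "alpha_db"
  out
}

#' Event-locked wave analysis
#'
#' For each trial containing a target or distractor, quantifies forward and
#' backward waves in the 500 ms before and the 500 ms after event onset (one
#' window each, surrogate-referenced, alpha-band averaged), assigns laterality
#' relative to the stimulus side (targets appear on the attended side,
#' distractors on the unattended side), and pair-normalizes. Trials whose
#' onset is closer than `window_s` to an epoch edge are skipped and counted.
#' A line x time map of dB around onset is returned alongside.
#'
#' @param epochs an [epoch_set()] whose metadata has `event_type`,
#'   `event_onset` (s, relative to trial onset) and `outcome`.
#' @param lines a [line_set()].
#' @param window_s window length in seconds.
#' @param band length-2 band (Hz) averaged for the summary table.
#' @param map_offsets window start offsets (s, relative to onset) for the
#'   line x time map.
#' @param n_shuffles,f_range,seed surrogate settings.
#' @return list with `table` (subject/trial/event/outcome/window/line values,
#'   normalized), `map` (event class x window offset x line mean dB),
#'   `n_skipped`.
#' @export
event_locked_waves <- function(epochs, lines, window_s = 0.5, band = c(8, 12),
                               map_offsets = seq(-0.5, 0.25, by = 0.25),
                               n_shuffles = 100, f_range = c(2, 45),
                               seed = NULL) {
  md <- epochs$metadata
  ev <- which(md$event_type %in% c("target", "distractor") & !is.na(md$event_onset))
  if (length(ev) == 0) .stopf("no event trials in epoch set")
  fs <- epochs$fs
  n_samp <- dim(epochs$data)[3]
  win <- round(window_s * fs)
  onset_smp <- round((md$event_onset[ev] - epochs$t_start) * fs) + 1
  ok <- onset_smp - win >= 1 & onset_smp + win - 1 <= n_samp
  skipped <- ev[!ok]
  ev <- ev[ok]; onset_smp <- onset_smp[ok]
  stim_side <- ifelse(md$event_type[ev] == "target", md$attended_side[ev],
                      ifelse(md$attended_side[ev] == "left", "right", "left"))
  rows <- NULL
  map_rows <- NULL
  for (i in seq_len(nrow(lines))) {
    labels <- line_electrodes(lines, lines$line_id[i])
    arr <- .line_array(epochs, labels)
    for (w in c("pre", "post")) {
      s0 <- if (w == "pre") onset_smp - win else onset_smp
      seg <- array(0, c(length(ev), length(labels), win))
      for (k in seq_along(ev)) seg[k, , ] <- arr[ev[k], , s0[k]:(s0[k] + win - 1)]
      res <- .line_wave_db(seg, fs, window_s, 0, f_range, n_shuffles,
                           seed = if (is.null(seed)) NULL else seed + 7 * i)
      inb <- res$freq >= band[1] & res$freq <= band[2]
      rows <- rbind(rows, data.frame(
        subject = md$subject[ev], trial = md$trial[ev],
        event_type = md$event_type[ev], outcome = md$outcome[ev],
        window = w, line_id = lines$line_id[i],
        laterality = .laterality(lines$hemisphere[i], stim_side),
        fw_db = rowMeans(res$fw_db[, inb, drop = FALSE]),
        bw_db = rowMeans(res$bw_db[, inb, drop = FALSE]),
        stringsAsFactors = FALSE))
    }
    for (off in map_offsets) {
      s0 <- onset_smp + round(off * fs)
      keep <- s0 >= 1 & s0 + win - 1 <= n_samp
      if (!any(keep)) next
      seg <- array(0, c(sum(keep), length(labels), win))
      kk <- which(keep)
      for (k in seq_along(kk)) seg[k, , ] <- arr[ev[kk[k]], , s0[kk[k]]:(s0[kk[k]] + win - 1)]
      res <- .line_wave_db(seg, fs, window_s, 0, f_range, n_shuffles,
                           seed = if (is.null(seed)) NULL else seed + 13 * i)
      inb <- res$freq >= band[1] & res$freq <= band[2]
      map_rows <- rbind(map_rows, data.frame(
        event_type = md$event_type[ev[kk]], outcome = md$outcome[ev[kk]],
        offset_s = off, line_id = lines$line_id[i],
        fw_db = rowMeans(res$fw_db[, inb, drop = FALSE]),
        bw_db = rowMeans(res$bw_db[, inb, drop = FALSE]),
        stringsAsFactors = FALSE))
    }
  }
  map <- if (is.null(map_rows)) NULL else
    stats::aggregate(cbind(fw_db, bw_db) ~ event_type + outcome + offset_s + line_id,
                     map_rows, mean)
  list(table = rows, map = map, n_skipped = length(skipped),
       skipped_trials = md$trial[skipped])
}

#' Aggregate and pair-normalize event-locked waves
#'
#' Averages the per-trial event table over trials within subject x condition
#' and applies the homologous-pair normalization per window.
#'
#' @param ev_table the `table` element of [event_locked_waves()].
#' @param lines the [line_set()].
#' @param by grouping column: `"event_type"` (target vs distractor) or
#'   `"outcome"` (hit vs miss, targets only).
#' @return Long data.frame with `normalized_db` per subject, condition,
#'   window, line, laterality and direction.
#' @export
event_band_table <- function(ev_table, lines, by = c("event_type", "outcome")) {
  by <- match.arg(by)
  tb <- ev_table
  if (by == "outcome") tb <- tb[tb$event_type == "target" & tb$outcome %in% c("hit", "miss"), ]
  li <- match(tb$line_id, lines$line_id)
  tb$pair_id <- ifelse(tb$laterality == "mid", "mid", lines$pair_id[li])
  long <- rbind(
    data.frame(tb[c("subject", "window", "pair_id", "laterality")],
               cond = tb[[by]], direction = "FW", db = tb$fw_db),
    data.frame(tb[c("subject", "window", "pair_id", "laterality")],
               cond = tb[[by]], direction = "BW", db = tb$bw_db))
  agg <- stats::aggregate(db ~ subject + cond + window + pair_id + laterality + direction,
                          long, mean)
  agg$normalized_db <- NA_real_
  lat <- which(agg$laterality != "mid")
  key <- paste(agg$subject, agg$cond, agg$window, agg$pair_id, agg$direction)[lat]
  for (k in unique(key)) {
    i <- lat[key == k]
    if (length(i) == 2) agg$normalized_db[i] <- agg$db[i] - mean(agg$db[i])
  }
  names(agg)[names(agg) == "db"] <- "value_db"
  agg
}
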
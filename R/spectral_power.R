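#' Morlet-wavelet time-frequency power
#'
#' Complex Morlet convolution per channel and frequency on a log-spaced grid
#' (default 30 frequencies over 1-45 Hz), with the cycle count interpolated
#' linearly in log-frequency from `cycle_range[1]` at the lowest to
#' `cycle_range[2]` at the highest frequency. Power is the squared magnitude
#' averaged over the trial, excluding half a wavelet support at each edge so
#' trial means are not biased by edge ramp-up. Wavelets are amplitude-
#' normalized: a pure sinusoid of amplitude A yields power A^2 at its
#' frequency.
#'
#' @param epochs an [epoch_set()].
#' @param channels channel labels to analyse (default: all non-EOG channels).
#' @param freqs explicit frequency vector (Hz); overrides `n_freqs`/`f_range`
#'   for the grid but keeps the cycle interpolation anchored to `f_range`.
#' @param n_freqs,f_range grid size and range.
#' @param cycle_range wavelet cycles at the range endpoints.
#' @param trials trial indices (default all).
#' @return list with `power` (trials x channels x freqs array of mean power),
#'   `freqs`, `cycles`, `channels`, `trials`.
#' @export
morlet_power <- function(epochs, channels = NULL, freqs = NULL, n_freqs = 30,
                         f_range = c(1, 45), cycle_range = c(1, 20),
                         trials = NULL) {
  if (is.null(channels))
    channels <- setdiff(epochs$channels, epochs$eog_channels)
  idx <- match(channels, epochs$channels)
  if (anyNA(idx)) .stopf("channel(s) not found: %s",
                         paste(channels[is.na(idx)], collapse = ", "))
  if (is.null(trials)) trials <- seq_len(n_trials(epochs))
  if (is.null(freqs))
    freqs <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_freqs))
  fs <- epochs$fs
  n_samp <- dim(epochs$data)[3]
  cyc <- cycle_range[1] + diff(cycle_range) *
    (log(freqs) - log(f_range[1])) / diff(log(f_range))
  sigma <- cyc / (2 * pi * freqs)
  margin <- ceiling(3 * sigma * fs)
  too_long <- which(2 * margin >= n_samp)
  if (length(too_long))
    .stopf("wavelet longer than epoch at %.3g Hz", freqs[too_long[1]])
  half <- margin
  L <- 2 * half + 1
  nfft <- n_samp + max(L) - 1
  kf <- vector("list", length(freqs))
  for (j in seq_along(freqs)) {
    tt <- (-half[j]:half[j]) / fs
    env <- exp(-tt^2 / (2 * sigma[j]^2))
    kern <- complex(modulus = env, argument = 2 * pi * freqs[j] * tt)
    kern <- kern * 2 / sum(env) # amplitude normalization
    kf[[j]] <- stats::fft(c(kern, rep(0, nfft - L[j])))
  }
  pow <- array(0, c(length(trials), length(channels), length(freqs)))
  n_ch <- length(channels)
  # batch trials: FFT-convolve all (channel, trial) columns of a chunk at once
  chunk <- max(1L, floor(3000 / n_ch))
  for (lo in seq(1, length(trials), by = chunk)) {
    ks <- lo:min(lo + chunk - 1, length(trials))
    sig <- matrix(0, nfft, n_ch * length(ks))
    for (i in seq_along(ks)) {
      sig[1:n_samp, (i - 1) * n_ch + seq_len(n_ch)] <-
        t(matrix(epochs$data[trials[ks[i]], idx, ], n_ch, n_samp))
    }
    Sf <- stats::mvfft(sig)
    for (j in seq_along(freqs)) {
      conv <- stats::mvfft(Sf * kf[[j]], inverse = TRUE) / nfft
      valid <- (half[j] + 1 + half[j]):(half[j] + n_samp - half[j])
      pw <- Mod(conv[valid, , drop = FALSE])^2
      pow[ks, , j] <- t(matrix(colMeans(pw), n_ch, length(ks)))
    }
  }
  list(power = pow, freqs = freqs, cycles = cyc, channels = channels,
       trials = epochs$metadata$trial[trials])
}

#' Electrodes of the occipital and frontal analysis regions
#'
#' @param lines a [line_set()]
#' @param occ_positions,front_positions line positions defining the regions.
#' @return Character vector of unique lateral region labels.
#' @export
region_electrodes <- function(lines, occ_positions = 1:2, front_positions = 6:7) {
  lat <- lines[lines$hemisphere != "mid", ]
  unique(unlist(lat[paste0("e", c(occ_positions, front_positions))]))
}

#' Regional alpha-power table
#'
#' Mean alpha-band (8-12 Hz grid frequencies) power per trial over the
#' occipital and frontal region electrodes of each hemisphere - the same
#' electrodes the wave analysis uses: by default the 2 most occipital and 2
#' most frontal positions of every lateral line. Laterality is assigned per
#' trial from the attended side.
#'
#' @param power result of [morlet_power()].
#' @param lines a [line_set()].
#' @param metadata epoch metadata with `trial`, `subject`, `attended_side`.
#' @param occ_positions,front_positions line positions (1 = most occipital)
#'   defining the regions.
#' @param alpha band limits in Hz.
#' @return data.frame `subject`, `trial`, `region`, `laterality`,
#'   `alpha_power`.
#' @export
alpha_table <- function(power, lines, metadata, occ_positions = 1:2,
                        front_positions = 6:7, alpha = c(8, 12)) {
  fsel <- which(power$freqs >= alpha[1] & power$freqs <= alpha[2])
  if (length(fsel) == 0) .stopf("no wavelet frequencies inside the alpha band")
  lat <- lines[lines$hemisphere != "mid", ]
  regions <- list()
  for (h in c("left", "right")) {
    ls <- lat[lat$hemisphere == h, ]
    occ <- unique(unlist(ls[paste0("e", occ_positions)]))
    fro <- unique(unlist(ls[paste0("e", front_positions)]))
    regions[[paste0("occipital.", h)]] <- occ
    regions[[paste0("frontal.", h)]] <- fro
  }
  out <- NULL
  for (nm in names(regions)) {
    chans <- intersect(regions[[nm]], power$channels)
    if (length(chans) == 0) .stopf("region %s has no channels in the power object", nm)
    ci <- match(chans, power$channels)
    val <- apply(power$power[, ci, fsel, drop = FALSE], 1, mean)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    out <- rbind(out, data.frame(trial = power$trials, region = parts[1],
                                 hemisphere = parts[2], alpha_power = val,
                                 stringsAsFactors = FALSE))
  }
  md <- metadata
  i <- match(out$trial, md$trial)
  out$subject <- md$subject[i]
  out$laterality <- .laterality(out$hemisphere, md$attended_side[i])
  out[c("subject", "trial", "region", "hemisphere", "laterality", "alpha_power")]
}

#' Alpha-power lateralization topography
#'
#' Per-channel mean alpha power difference, attend-left minus attend-right,
#' plus a folded map in which attend-left trials are included by mirroring
#' every lateral channel to its homologue (midline channels are fold fixed
#' points), giving an attend-right-referenced topography.
#'
#' @param power result of [morlet_power()].
#' @param metadata epoch metadata with `trial` and `attended_side`.
#' @param alpha band limits (Hz).
#' @return data.frame `channel`, `diff` (left - right), `folded`.
#' @export
lateralization_topography <- function(power, metadata, alpha = c(8, 12)) {
  fsel <- which(power$freqs >= alpha[1] & power$freqs <= alpha[2])
  side <- metadata$attended_side[match(power$trials, metadata$trial)]
  if (!all(c("left", "right") %in% side))
    .stopf("both attention conditions are required")
  ap <- apply(power$power[, , fsel, drop = FALSE], c(1, 2), mean) # trials x ch
  ml <- colMeans(ap[side == "left", , drop = FALSE])
  mr <- colMeans(ap[side == "right", , drop = FALSE])
  mirror <- mirror_label(power$channels)
  mi <- match(mirror, power$channels)
  if (anyNA(mi)) .stopf("no mirror channel for: %s",
                        paste(power$channels[is.na(mi)], collapse = ", "))
  folded <- (mr + ml[mi]) / 2
  data.frame(channel = power$channels, diff = ml - mr, folded = folded,
             stringsAsFactors = FALSE)
}
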
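#' Traveling-wave component description
#'
#' One plane-wave component on an electrode line: electrode k of the line
#' (k = 0 most occipital) receives `amplitude * cos(2*pi*f*t - k*phase_step +
#' phase)` over `[onset, offset)`. A positive `phase_step` means the phase
#' increases toward frontal electrodes, i.e. a forward (occipital-to-frontal)
#' wave; negative steps give backward waves.
#'
#' @param temporal_freq temporal frequency in Hz, must lie in (0, fs/2).
#' @param amplitude amplitude in signal units (arbitrary; the simulator's
#'   background noise has unit standard deviation).
#' @param phase_step phase advance per electrode in radians, |phase_step| < pi
#'   so the 7-electrode spatial sampling is unaliased.
#' @param line_id id of the line the component lives on.
#' @param onset,offset active interval in seconds within the trial.
#' @param phase phase offset in radians at t = 0, electrode 0.
#' @return A `wave_component` list.
#' @export
wave_component <- function(temporal_freq, amplitude, phase_step, line_id = NA,
                           onset = 0, offset = Inf, phase = 0) {
  if (!is.finite(temporal_freq) || temporal_freq <= 0)
    .stopf("temporal_freq must be positive")
  if (abs(phase_step) >= pi)
    .stopf("|phase_step| must be < pi (spatially aliased otherwise)")
  structure(list(temporal_freq = temporal_freq, amplitude = amplitude,
                 phase_step = phase_step, line_id = line_id, onset = onset,
                 offset = offset, phase = phase),
            class = "wave_component")
}

#' 1/f background EEG noise
#'
#' Generates mutually independent channels whose expected power spectral
#' density falls as 1/f^exponent over (0, fs/2], by shaping a white complex
#' spectrum and inverse-transforming. Each channel is standardized to zero
#' mean and standard deviation `amplitude`; `exponent = 0` gives white noise.
#'
#' @param n_channels,n_samples array dimensions (n_samples >= 2).
#' @param fs sampling rate in Hz.
#' @param exponent spectral exponent, >= 0.
#' @param amplitude per-channel standard deviation (0 gives an all-zero array).
#' @param seed optional integer seed (caller RNG state is preserved).
#' @param transpose return channels x samples (default); `FALSE` returns the
#'   samples x channels layout without the final copy (internal fast path).
#' @return `n_channels x n_samples` matrix (unless `transpose = FALSE`).
#' @export
generate_background <- function(n_channels, n_samples, fs, exponent = 1,
                                amplitude = 1, seed = NULL, transpose = TRUE) {
  if (!.is_count(n_channels) || !.is_count(n_samples) || n_samples < 2)
    .stopf("n_channels and n_samples must be positive counts (n_samples >= 2)")
  if (exponent < 0) .stopf("exponent must be >= 0")
  if (amplitude == 0) {
    return(if (transpose) matrix(0, n_channels, n_samples)
           else matrix(0, n_samples, n_channels))
  }
  .with_seed(seed, {
    n <- n_samples
    npos <- floor(n / 2)
    f <- (1:npos) * fs / n
    gain <- f^(-exponent / 2)
    spec <- matrix(0i, n, n_channels)
    re <- matrix(stats::rnorm(npos * n_channels), npos, n_channels)
    im <- matrix(stats::rnorm(npos * n_channels), npos, n_channels)
    spec[2:(npos + 1), ] <- gain * complex(real = re, imaginary = im)
    if (n %% 2 == 0) spec[npos + 1, ] <- gain[npos] * re[npos, ] # Nyquist bin real
    if (n > 2) {
      neg <- seq(n, n - (ceiling(n / 2) - 1) + 1)
      spec[neg, ] <- Conj(spec[2:(length(neg) + 1), ])
    }
    # two real channels per inverse FFT: conj-symmetric spectra S1, S2 give
    # ifft(S1 + i*S2) = x1 + i*x2 with x1, x2 real
    x <- matrix(0, n, n_channels)
    m2 <- floor(n_channels / 2)
    if (m2 > 0) {
      Y <- stats::mvfft(spec[, 1:m2, drop = FALSE] +
                          1i * spec[, m2 + (1:m2), drop = FALSE],
                        inverse = TRUE) / n
      x[, 1:m2] <- Re(Y)
      x[, m2 + (1:m2)] <- Im(Y)
    }
    if (n_channels %% 2 == 1)
      x[, n_channels] <- Re(stats::fft(spec[, n_channels], inverse = TRUE)) / n
    # standardize: mean is 0 by construction (no DC), scale sd to amplitude
    sds <- sqrt(colSums(x^2) / (n - 1))
    x <- x * rep(amplitude / sds, each = n)
    if (transpose) t(x) else x
  })
}

#' Inject a plane-wave component into a channel x sample array
#'
#' Additive: electrode k of the line (ordered occipital to frontal) gains
#' `amplitude * cos(2*pi*f*t - k*phase_step + phase)` over `[onset, offset)`;
#' all other channels are untouched.
#'
#' @param signals channels x samples numeric matrix.
#' @param line integer indices of the line's channels in `signals`, ordered
#'   occipital to frontal.
#' @param comp a [wave_component()].
#' @param fs sampling rate in Hz.
#' @return The modified matrix.
#' @export
inject_wave <- function(signals, line, comp, fs) {
  .inject_wave_pos(signals, line, seq_along(line), comp, fs)
}

# general form: electrode `rows[i]` sits at occipito-frontal position
# `pos[i]` (1-based) and lags by (pos[i]-1) * phase_step
.inject_wave_pos <- function(signals, rows, pos, comp, fs) {
  stopifnot(inherits(comp, "wave_component"))
  if (comp$temporal_freq >= fs / 2)
    .stopf("temporal_freq must be below fs/2 = %g", fs / 2)
  if (any(rows < 1 | rows > nrow(signals))) .stopf("line indices out of range")
  line <- rows
  n <- ncol(signals)
  t <- (seq_len(n) - 1) / fs
  on <- t >= comp$onset & t < comp$offset
  if (!any(on)) return(signals)
  ph <- 2 * pi * comp$temporal_freq * t[on] + comp$phase
  # electrode at position p (1-based) lags by (p-1) * phase_step
  block <- comp$amplitude *
    cos(matrix(ph, length(line), length(ph), byrow = TRUE) -
          (pos - 1) * comp$phase_step)
  if (all(on)) {
    signals[line, ] <- signals[line, ] + block
  } else {
    signals[line, on] <- signals[line, on] + block
  }
  signals
}

#' Simulation configuration
#'
#' The defaults state the emulated experiment: 5-s trials at 256 Hz on a
#' 64-channel montage, 1/f background of unit standard deviation, alpha-band
#' (10 Hz) plane waves running along the occipito-frontal lines in both
#' directions, attention gains multiplying contralateral-forward and
#' ipsilateral-backward alpha amplitude, theta-forward / low-beta-backward /
#' gamma-forward components reproducing the resting spectral profile,
#' target/distractor events of 100 ms in half the trials, and an ~80% hit
#' rate. `n_trials_per_side = 300` mirrors the experiment's 600 trials;
#' analyses in tests pass smaller values for runtime only.
#'
#' @param n_subjects,n_trials_per_side design size.
#' @param trial_duration,fs trial length (s) and sampling rate (Hz);
#'   `trial_duration * fs` must be an integer.
#' @param one_over_f_exponent,noise_amplitude background 1/f spectral slope
#'   and per-channel standard deviation.
#' @param alpha_amp,theta_amp,low_beta_amp,gamma_amp wave amplitudes (signal
#'   units) of the 10 Hz, 6 Hz, 18 Hz and 32 Hz components.
#' @param standing_alpha_amp amplitude of the spatially uniform (standing,
#'   zero phase-step) alpha oscillation per hemisphere; carries alpha power
#'   but no direction information.
#' @param phase_step phase advance magnitude per electrode (radians).
#' @param attention_gain_fw_contra,attention_gain_bw_ipsi multiplicative
#'   gains (>= 0) on contralateral forward / ipsilateral backward alpha wave
#'   amplitude; 1 disables the attention effect.
#' @param alpha_ipsi_gain gain on standing-alpha amplitude ipsilateral to the
#'   attended side (the classical power lateralization).
#' @param band_profile include the theta/low-beta/gamma directional
#'   components.
#' @param event_rate fraction of trials containing a target or distractor.
#' @param event_duration event length in seconds (0.1 = 100 ms flash).
#' @param event_transient_amp amplitude of the broadband Gaussian-windowed
#'   onset transient on occipital electrodes contralateral to the stimulus.
#' @param event_fw_gain_post gain on contralateral forward alpha amplitude in
#'   the 500 ms after event onset (1 = no event-locked wave change).
#' @param hit_rate probability of detecting a target.
#' @param hit_slope logistic-link slope tying hit probability to the trial's
#'   attention factor; with slope != 0, event trials draw a lognormal
#'   attention factor that multiplies contralateral-forward (and divides
#'   ipsilateral-backward) alpha amplitude, so misses co-occur with reduced
#'   contralateral forward waves. 0 = pure Bernoulli.
#' @param attention_cv log-sd of the event-trial attention factor (used only
#'   when `hit_slope != 0`).
#' @param wave_power_coupling correlation in [0, 1] between the trial-level
#'   log-amplitude of the coupled wave component and the standing-alpha
#'   log-amplitude, realized through a shared Gaussian latent factor. At 0 the
#'   coupled wave amplitude is constant across trials, so trial-by-trial
#'   wave-power correlations are exactly null-calibrated.
#' @param coupling_target which wave amplitude the latent factor drives:
#'   `"bw_contra"` (default), `"bw_ipsi"`, `"fw_contra"` or `"fw_ipsi"`.
#' @param coupling_cv log-sd scale of the latent amplitude modulation.
#' @param eog_artifact_rate fraction of trials with a saccade-like EOG ramp.
#' @param eog_amp artifact amplitude (same units; nominally microvolts).
#' @param channels `"montage"` (full 64 + EOG) or `"lines"` (only electrodes
#'   used by the line set + EOG; faster for wave-only simulations).
#' @param keep_components store every injected component per trial in the
#'   ground truth (memory-heavy; for additivity checks).
#' @param seed integer seed; identical configs give bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 16, n_trials_per_side = 300,
                       trial_duration = 5, fs = 256,
                       one_over_f_exponent = 1, noise_amplitude = 1,
                       alpha_amp = 0.5, theta_amp = 0.3, low_beta_amp = 0.25,
                       gamma_amp = 0.15, standing_alpha_amp = 1,
                       phase_step = pi / 4,
                       attention_gain_fw_contra = 1.5,
                       attention_gain_bw_ipsi = 1.5,
                       alpha_ipsi_gain = 1.2, band_profile = TRUE,
                       event_rate = 0.5, event_duration = 0.1,
                       event_transient_amp = 1, event_fw_gain_post = 1,
                       hit_rate = 0.8, hit_slope = 0, attention_cv = 0.3,
                       wave_power_coupling = 0.3,
                       coupling_target = c("bw_contra", "bw_ipsi",
                                           "fw_contra", "fw_ipsi"),
                       coupling_cv = 0.3,
                       eog_artifact_rate = 0.05, eog_amp = 150,
                       channels = c("montage", "lines"),
                       keep_components = FALSE, seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_trials_per_side = n_trials_per_side,
              trial_duration = trial_duration, fs = fs,
              one_over_f_exponent = one_over_f_exponent,
              noise_amplitude = noise_amplitude, alpha_amp = alpha_amp,
              theta_amp = theta_amp, low_beta_amp = low_beta_amp,
              gamma_amp = gamma_amp, standing_alpha_amp = standing_alpha_amp,
              phase_step = phase_step,
              attention_gain_fw_contra = attention_gain_fw_contra,
              attention_gain_bw_ipsi = attention_gain_bw_ipsi,
              alpha_ipsi_gain = alpha_ipsi_gain, band_profile = band_profile,
              event_rate = event_rate, event_duration = event_duration,
              event_transient_amp = event_transient_amp,
              event_fw_gain_post = event_fw_gain_post,
              hit_rate = hit_rate, hit_slope = hit_slope,
              attention_cv = attention_cv,
              wave_power_coupling = wave_power_coupling,
              coupling_target = match.arg(coupling_target),
              coupling_cv = coupling_cv,
              eog_artifact_rate = eog_artifact_rate, eog_amp = eog_amp,
              channels = match.arg(channels),
              keep_components = keep_components, seed = seed)
  probs <- c("event_rate", "hit_rate", "eog_artifact_rate")
  for (p in probs) if (cfg[[p]] < 0 || cfg[[p]] > 1) .stopf("%s must be in [0,1]", p)
  if (abs(cfg$wave_power_coupling) > 1) .stopf("wave_power_coupling must be in [-1,1]")
  if (abs(cfg$trial_duration * cfg$fs - round(cfg$trial_duration * cfg$fs)) > 1e-9)
    .stopf("trial_duration * fs must be an integer number of samples")
  if (cfg$attention_gain_fw_contra < 0 || cfg$attention_gain_bw_ipsi < 0)
    .stopf("attention gains must be >= 0")
  if (cfg$event_rate > 0 &&
      cfg$trial_duration < 1 + cfg$event_duration)
    .stopf("trials too short for events: need >= 0.5 s before onset and 0.5 s after")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate one subject's epochs
#'
#' @param config a [sim_config()].
#' @param subject subject id (integer).
#' @param lines a [line_set()].
#' @param subject_seed seed for this subject (derived from `config$seed` by
#'   [simulate_experiment()]).
#' @return list with `epochs` (an [epoch_set()]) and `ground_truth`
#'   (one data.frame row per trial; component lists attached as the
#'   `components` attribute when `keep_components = TRUE`).
#' @export
simulate_subject <- function(config, subject, lines = default_line_set(),
                             subject_seed = config$seed) {
  cfg <- config
  fs <- cfg$fs
  n_samp <- round(cfg$trial_duration * fs)
  eog <- c("EXG1", "EXG2", "EXG3")
  chans <- if (cfg$channels == "montage") biosemi64_labels() else
    line_set_electrodes(lines)
  chans <- c(chans, eog)
  n_ch <- length(chans)
  hemi_ch <- .label_hemisphere(chans)

  n_side <- cfg$n_trials_per_side
  n_tr <- 2L * n_side
  t <- (seq_len(n_samp) - 1) / fs

  .with_seed(subject_seed, {
    side <- sample(rep(c("left", "right"), n_side))
    has_event <- stats::runif(n_tr) < cfg$event_rate
    ev_type <- ifelse(has_event,
                      ifelse(stats::runif(n_tr) < 0.5, "target", "distractor"),
                      "none")
    ev_onset <- rep(NA_real_, n_tr)
    if (any(has_event))
      ev_onset[has_event] <- stats::runif(sum(has_event), 0.5,
                                          cfg$trial_duration - cfg$event_duration - 0.5)
    # latent wave/power coupling: shared factor z; the coupled wave log-amp
    # loads with sqrt(rho) so corr(log wave amp, log alpha amp) = rho and the
    # wave amplitude is constant when rho = 0
    rho <- cfg$wave_power_coupling
    z <- stats::rnorm(n_tr)
    eps <- stats::rnorm(n_tr)
    # corr(lw, la) = rho exactly on the log scale; wave amplitude is constant
    # when rho = 0, keeping the trial-by-trial null clean
    lw <- cfg$coupling_cv * sqrt(abs(rho)) * z
    la <- cfg$coupling_cv * (rho * z + sqrt(1 - rho^2) * eps)
    m_wave <- exp(lw - cfg$coupling_cv^2 * abs(rho) / 2)
    m_alpha <- exp(la - cfg$coupling_cv^2 / 2)
    # event-trial attention factor (only active with a logistic hit link)
    att <- if (cfg$hit_slope != 0)
      exp(stats::rnorm(n_tr, 0, cfg$attention_cv)) else rep(1, n_tr)
    p_hit <- stats::plogis(stats::qlogis(cfg$hit_rate) + cfg$hit_slope * log(att))
    outcome <- ifelse(ev_type == "target",
                      ifelse(stats::runif(n_tr) < p_hit, "hit", "miss"), "n/a")
    eog_bad <- stats::runif(n_tr) < cfg$eog_artifact_rate

    comp_list <- if (cfg$keep_components) vector("list", n_tr) else NULL
    if (cfg$keep_components) for (tr in seq_len(n_tr)) comp_list[[tr]] <- list()
    stim_side <- ifelse(ev_type == "distractor",
                        ifelse(side == "left", "right", "left"), side)

    # background noise, batched over trials as (k*n_ch) independent channels
    # per chunk, reshaped to trials x channels x samples (chunked to bound
    # the FFT workspace)
    dat <- array(0, c(n_tr, n_ch, n_samp))
    chunk <- max(1L, min(n_tr, floor(6000 / n_ch)))
    for (lo in seq(1, n_tr, by = chunk)) {
      trs <- lo:min(lo + chunk - 1, n_tr)
      bg <- generate_background(length(trs) * n_ch, n_samp, fs,
                                cfg$one_over_f_exponent, cfg$noise_amplitude,
                                transpose = FALSE)
      dat[trs, , ] <- aperm(array(bg, c(n_samp, n_ch, length(trs))), c(3, 2, 1))
    }

    # one traveling wave per hemisphere and component: every electrode's
    # phase lag is set by its occipito-frontal position, so all lines of the
    # hemisphere carry the same coherent plane wave (overlapping lines see
    # one wave, not interfering copies). Batched across trials: with trial
    # phase theta a component contributes amp*(C*cos(theta) - S*sin(theta))
    # for position templates C/S - two rank-1 updates per component.
    pos_map <- hemisphere_positions(lines)
    for (h in c("left", "right", "mid")) {
      pm <- pos_map[pos_map$hemisphere == h, ]
      rows <- match(pm$label, chans)
      k <- pm$position
      n_e <- length(rows)
      lat <- .laterality(rep(h, n_tr), side)
      g_fw <- ifelse(lat == "contra", cfg$attention_gain_fw_contra, 1)
      g_bw <- ifelse(lat == "ipsi", cfg$attention_gain_bw_ipsi, 1)
      m_fw <- ifelse(paste0("fw_", lat) == cfg$coupling_target, m_wave, 1)
      m_bw <- ifelse(paste0("bw_", lat) == cfg$coupling_target, m_wave, 1)
      a_fw <- ifelse(lat == "contra", att, 1)
      a_bw <- ifelse(lat == "ipsi", 1 / att, 1)
      comps_h <- list(list(10, cfg$phase_step, cfg$alpha_amp * g_fw * m_fw * a_fw),
                      list(10, -cfg$phase_step, cfg$alpha_amp * g_bw * m_bw * a_bw))
      if (cfg$band_profile) {
        comps_h <- c(comps_h,
                     list(list(6, cfg$phase_step, rep(cfg$theta_amp, n_tr)),
                          list(18, -cfg$phase_step, rep(cfg$low_beta_amp, n_tr)),
                          list(32, cfg$phase_step, rep(cfg$gamma_amp, n_tr))))
      }
      acc <- NULL
      for (cc in comps_h) {
        freq <- cc[[1]]; step <- cc[[2]]; amps <- cc[[3]]
        if (!any(amps > 0)) next
        theta <- stats::runif(n_tr, 0, 2 * pi)
        base <- matrix(2 * pi * freq * t, n_e, n_samp, byrow = TRUE) -
          (k - 1) * step
        contrib <- tcrossprod(amps * cos(theta), as.vector(cos(base))) -
          tcrossprod(amps * sin(theta), as.vector(sin(base)))
        acc <- if (is.null(acc)) contrib else acc + contrib
        if (cfg$keep_components) {
          for (tr in which(amps > 0)) {
            comp_list[[tr]][[length(comp_list[[tr]]) + 1]] <-
              wave_component(freq, amps[tr], step, h, phase = theta[tr])
          }
        }
      }
      if (!is.null(acc))
        dat[, rows, ] <- dat[, rows, ] + array(acc, c(n_tr, n_e, n_samp))
    }

    # standing alpha: spatially uniform per hemisphere (invisible to the
    # directional analysis), stronger ipsilateral to the attended side
    cos0 <- cos(2 * pi * 10 * t); sin0 <- sin(2 * pi * 10 * t)
    for (h in c("left", "right", "mid")) {
      amps <- cfg$standing_alpha_amp * m_alpha
      if (h == "mid") amps <- amps * (1 + cfg$alpha_ipsi_gain) / 2
      else amps <- amps * ifelse(side == h, cfg$alpha_ipsi_gain, 1)
      rows <- which(hemi_ch == h & !(chans %in% eog))
      if (length(rows) == 0 || all(amps <= 0)) next
      theta <- stats::runif(n_tr, 0, 2 * pi)
      contrib <- tcrossprod(amps * cos(theta), cos0) -
        tcrossprod(amps * sin(theta), sin0)
      for (r in rows) dat[, r, ] <- dat[, r, ] + contrib
    }

    # event-locked wave boost and broadband onset transient, per event trial
    ev_trials <- which(ev_type != "none")
    for (tr in ev_trials) {
      sig <- matrix(dat[tr, , ], n_ch, n_samp)
      contra_h <- if (stim_side[tr] == "left") "right" else "left"
      pm <- pos_map[pos_map$hemisphere == contra_h, ]
      if (cfg$event_fw_gain_post != 1) {
        # hemisphere contra to the stimulus: contra to attention for targets,
        # ipsi for distractors
        g_fw <- if (contra_h != side[tr]) cfg$attention_gain_fw_contra else 1
        extra <- cfg$alpha_amp * g_fw * (cfg$event_fw_gain_post - 1)
        if (extra != 0) {
          cmp <- wave_component(10, extra, cfg$phase_step, contra_h,
                                onset = ev_onset[tr],
                                offset = min(ev_onset[tr] + 0.5, cfg$trial_duration),
                                phase = stats::runif(1, 0, 2 * pi))
          if (cfg$keep_components)
            comp_list[[tr]][[length(comp_list[[tr]]) + 1]] <- cmp
          sig <- .inject_wave_pos(sig, match(pm$label, chans), pm$position, cmp, fs)
        }
      }
      # 100-ms broadband burst under a 10-ms-sd Gaussian envelope on the
      # occipital electrodes contralateral to the stimulus
      if (cfg$event_transient_amp > 0) {
        occ <- match(pm$label[pm$position <= 2], chans)
        env <- exp(-((t - ev_onset[tr] - cfg$event_duration / 2)^2) / (2 * 0.01^2))
        act <- t >= ev_onset[tr] & t < ev_onset[tr] + cfg$event_duration
        env[!act] <- 0
        for (r in occ) {
          sig[r, ] <- sig[r, ] +
            cfg$event_transient_amp * env * stats::rnorm(n_samp)
        }
      }
      dat[tr, , ] <- sig
    }

    # EOG channels: measurement noise plus saccade-like ramps in a fraction
    # of trials
    eog_rows <- match(eog, chans)
    dat[, eog_rows, ] <- dat[, eog_rows, ] +
      array(stats::rnorm(n_tr * 3 * n_samp, 0, 5), c(n_tr, 3, n_samp))
    for (tr in which(eog_bad)) {
      onset_s <- stats::runif(1, 0.5, cfg$trial_duration - 1)
      ramp <- pmin(pmax((t - onset_s) / 0.05, 0), 1) * cfg$eog_amp
      dat[tr, eog_rows[1], ] <- dat[tr, eog_rows[1], ] + ramp
    }

    md <- data.frame(subject = subject, trial = seq_len(n_tr),
                     attended_side = side, event_type = ev_type,
                     event_onset = ev_onset, outcome = outcome,
                     stringsAsFactors = FALSE)
    gt <- cbind(md, data.frame(wave_amp_factor = m_wave,
                               alpha_amp_factor = m_alpha,
                               attention_factor = att,
                               eog_artifact = eog_bad))
    if (cfg$keep_components) attr(gt, "components") <- comp_list
    list(epochs = epoch_set(dat, fs, chans, md, t_start = 0, eog_channels = eog),
         ground_truth = gt)
  })
}

#' Simulate a complete multi-subject experiment
#'
#' Balanced attended-left / attended-right trials per subject, with wave
#' structure, events and behavioral labels per the configuration. Identical
#' seeds give bit-identical output.
#'
#' @inheritParams simulate_subject
#' @return list with `epochs` (all subjects' trials in one [epoch_set()]) and
#'   `ground_truth` (one row per trial).
#' @export
simulate_experiment <- function(config, lines = default_line_set()) {
  seeds <- .with_seed(config$seed,
                      sample.int(.Machine$integer.max - 1, config$n_subjects))
  subs <- lapply(seq_len(config$n_subjects), function(s)
    simulate_subject(config, s, lines, subject_seed = seeds[s]))
  gt <- do.call(rbind, lapply(subs, `[[`, "ground_truth"))
  rownames(gt) <- NULL
  comp <- unlist(lapply(subs, function(x) attr(x$ground_truth, "components")),
                 recursive = FALSE)
  epochs <- bind_epochs(lapply(subs, `[[`, "epochs"))
  # trial ids globally unique across subjects (within-subject index kept)
  gt$trial_within <- gt$trial
  gt$trial <- seq_len(nrow(gt))
  epochs$metadata$trial_within <- epochs$metadata$trial
  epochs$metadata$trial <- seq_len(nrow(epochs$metadata))
  if (config$keep_components) attr(gt, "components") <- comp
  list(epochs = epochs, ground_truth = gt)
}
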
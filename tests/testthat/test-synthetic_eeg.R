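test_that("background noise has the requested spectral exponent", {
  # exponent 0: white, flat spectrum
  x0 <- generate_background(200, 1280, 256, exponent = 0, amplitude = 1, seed = 1)
  expect_lt(abs(psd_slope(x0, 256)), 0.1)
  # exponent 1: 1/f, log-log slope -1 +- 0.1 over 2-45 Hz
  x1 <- generate_background(200, 1280, 256, exponent = 1, amplitude = 1, seed = 2)
  expect_lt(abs(psd_slope(x1, 256) + 1), 0.1)
  # zero mean, unit sd per channel; zero amplitude -> zero array
  expect_lt(max(abs(rowMeans(x1))), 1e-10)
  expect_equal(unname(apply(x1[1:5, ], 1, stats::sd)), rep(1, 5))
  expect_equal(generate_background(3, 64, 256, amplitude = 0),
               matrix(0, 3, 64))
  expect_error(generate_background(0, 64, 256), "count")
  expect_error(generate_background(3, 64, 256, exponent = -1), ">= 0")
})

test_that("inject_wave adds the stated plane wave and nothing else", {
  fs <- 256
  sig <- matrix(0, 10, 256)
  tt <- (0:255) / fs
  # zero phase step: identical sinusoid on all line electrodes
  cmp <- wave_component(10, 2, 0)
  out <- inject_wave(sig, 2:8, cmp, fs)
  for (r in 2:8) expect_equal(out[r, ], 2 * cos(2 * pi * 10 * tt))
  expect_equal(out[c(1, 9, 10), ], sig[c(1, 9, 10), ]) # untouched
  # explicit phase/step/windowing
  cmp2 <- wave_component(8, 1, pi / 4, onset = 0.25, offset = 0.75, phase = 1)
  out2 <- inject_wave(sig, 2:8, cmp2, fs)
  on <- tt >= 0.25 & tt < 0.75
  expect_equal(out2[4, on], cos(2 * pi * 8 * tt[on] + 1 - 2 * pi / 4))
  expect_true(all(out2[4, !on] == 0))
  # validation
  expect_error(wave_component(10, 1, pi), "aliased")
  expect_error(inject_wave(sig, 2:8, wave_component(200, 1, 0.1), fs), "fs/2")
})

test_that("injected forward wave is classified forward by the 2D-FFT", {
  map <- plane_wave_map(10, +pi / 4)
  sp <- fft2d_directional(map, 256)
  at10 <- sp[sp$freq == 10, ]
  expect_gt(at10$fw_raw / at10$bw_raw, 10)
  # two opposite-direction components of equal amplitude: FW ~ BW within 1%
  map2 <- plane_wave_map(10, +pi / 4, phase = 0.7) +
    plane_wave_map(10, -pi / 4, phase = 2.1)
  sp2 <- fft2d_directional(map2, 256)
  at <- sp2[sp2$freq == 10, ]
  expect_lt(abs(at$fw_raw / at$bw_raw - 1), 0.01)
})

test_that("simulation is deterministic and balanced", {
  cfg <- sim_config(n_subjects = 2, n_trials_per_side = 4, channels = "lines",
                    seed = 42)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$epochs$data, b$epochs$data)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_equal(unname(table(a$ground_truth$attended_side,
                            a$ground_truth$subject)["left", ]), c(4, 4))
  # one ground-truth record per trial
  expect_equal(nrow(a$ground_truth), n_trials(a$epochs))
  expect_identical(a$ground_truth$trial, a$epochs$metadata$trial)
})

test_that("with zero noise the output is exactly the sum of injected parts", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_side = 2, channels = "lines",
                    noise_amplitude = 0, standing_alpha_amp = 0,
                    event_rate = 0, eog_artifact_rate = 0,
                    keep_components = TRUE, seed = 9)
  sim <- simulate_subject(cfg, 1, subject_seed = 5)
  ep <- sim$epochs
  pm <- hemisphere_positions(default_line_set())
  eeg <- setdiff(ep$channels, ep$eog_channels)
  for (tr in seq_len(n_trials(ep))) {
    rec <- matrix(0, length(ep$channels), dim(ep$data)[3])
    for (cmp in attr(sim$ground_truth, "components")[[tr]]) {
      hm <- pm[pm$hemisphere == cmp$line_id, ]
      rec <- twaves:::.inject_wave_pos(rec, match(hm$label, ep$channels),
                                       hm$position, cmp, ep$fs)
    }
    got <- ep$data[tr, match(eeg, ep$channels), ]
    want <- rec[match(eeg, ep$channels), ]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("behavioral labels track configuration", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_side = 300, channels = "lines",
                    trial_duration = 2, event_rate = 1, hit_rate = 0.8,
                    band_profile = FALSE, eog_artifact_rate = 0, seed = 11)
  sim <- simulate_subject(cfg, 1, subject_seed = 2)
  gt <- sim$ground_truth
  tg <- gt[gt$event_type == "target", ]
  expect_gt(nrow(tg), 200)
  expect_lt(abs(mean(tg$outcome == "hit") - 0.8), 0.06)
  expect_true(all(gt$event_onset >= 0.5 &
                    gt$event_onset <= 2 - cfg$event_duration - 0.5))
})

test_that("latent factor couples wave and alpha amplitudes at the set level", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_side = 150, channels = "lines",
                    trial_duration = 1, wave_power_coupling = 0.5,
                    band_profile = FALSE, event_rate = 0,
                    eog_artifact_rate = 0, seed = 3)
  gt <- simulate_subject(cfg, 1, subject_seed = 8)$ground_truth
  r <- stats::cor(log(gt$wave_amp_factor), log(gt$alpha_amp_factor))
  expect_lt(abs(r - 0.5), 0.15)
  # zero coupling: wave amplitude is constant across trials (clean null)
  cfg0 <- sim_config(n_subjects = 1, n_trials_per_side = 20, channels = "lines",
                     trial_duration = 1, wave_power_coupling = 0,
                     band_profile = FALSE, event_rate = 0,
                     eog_artifact_rate = 0, seed = 3)
  gt0 <- simulate_subject(cfg0, 1, subject_seed = 8)$ground_truth
  expect_equal(stats::sd(gt0$wave_amp_factor), 0)
})

test_that("epoch set round-trips through the CSV container", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_side = 1, channels = "lines",
                    trial_duration = 0.5, event_rate = 0, seed = 2)
  ep <- simulate_subject(cfg, 1, subject_seed = 4)$epochs
  stem <- file.path(tempdir(), "ep_roundtrip")
  write_epoch_set(ep, stem)
  back <- read_epoch_set(stem)
  expect_equal(back$data, ep$data, tolerance = 1e-12)
  expect_equal(back$channels, ep$channels)
  expect_equal(back$fs, ep$fs)
  expect_equal(back$metadata$attended_side, ep$metadata$attended_side)
})
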
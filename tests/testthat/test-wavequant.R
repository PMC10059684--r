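test_that("window extraction follows the stated geometry", {
  m <- matrix(0, 7, 1280)
  w <- extract_windows(m, 256)
  expect_equal(length(w), 19) # floor((1280-128)/64)+1
  expect_true(all(vapply(w, ncol, 0) == 128))
  expect_equal(length(extract_windows(matrix(0, 7, 128), 256)), 1)
  expect_error(extract_windows(m, 256, win_s = 0.5, overlap_s = 0.5), "overlap")
  expect_error(extract_windows(matrix(0, 7, 64), 256), "shorter")
})

test_that("quadrant maxima match the DFT-by-definition oracle", {
  fs <- 256
  maps <- list(forward = plane_wave_map(8, +pi / 4),
               backward = plane_wave_map(12, -pi / 3, phase = 0.4),
               noise = {
                 set.seed(7)
                 matrix(stats::rnorm(7 * 128), 7, 128)
               })
  for (nm in names(maps)) {
    map <- maps[[nm]]
    got <- fft2d_directional(map, fs)
    want <- oracle_fft2d(map, fs)
    expect_equal(got$freq, want$freq)
    expect_lt(max(abs(got$fw_raw - want$fw_raw)) / max(want$fw_raw), 1e-9)
    expect_lt(max(abs(got$bw_raw - want$bw_raw)) / max(want$bw_raw), 1e-9)
  }
  # a forward wave peaks in the forward quadrant at its own frequency
  spf <- fft2d_directional(maps$forward, fs)
  expect_equal(spf$freq[which.max(spf$fw_raw)], 8)
})

test_that("electrode reversal swaps FW and BW bit-for-bit; time reversal to rounding", {
  set.seed(8)
  for (i in 1:5) {
    map <- matrix(stats::rnorm(7 * 128), 7, 128) + plane_wave_map(10, pi / 4)
    a <- fft2d_directional(map, 256)
    b <- fft2d_directional(map[7:1, ], 256)
    expect_identical(a$fw_raw, b$bw_raw)
    expect_identical(a$bw_raw, b$fw_raw)
    d <- fft2d_directional(map[, 128:1], 256)
    expect_equal(d$fw_raw, a$bw_raw, tolerance = 1e-12)
    expect_equal(d$bw_raw, a$fw_raw, tolerance = 1e-12)
  }
  # spatially constant map: after k_s = 0 exclusion FW equals BW
  mc <- matrix(rep(cos(2 * pi * 10 * (0:127) / 256), each = 7), 7, 128)
  spc <- fft2d_directional(mc, 256)
  expect_equal(spc$fw_raw, spc$bw_raw, tolerance = 1e-10)
  expect_error(fft2d_directional(matrix(c(NA, stats::rnorm(7 * 128 - 1)), 7, 128),
                                 256), "NA")
})

test_that("composed spatial/temporal transform satisfies Parseval", {
  set.seed(9)
  for (i in 1:3) {
    map <- matrix(stats::rnorm(7 * 64), 7, 64)
    Tfft <- t(stats::mvfft(t(map)))
    F2 <- twaves:::.spatial_dft_matrix(7) %*% Tfft
    expect_equal(sum(Mod(F2)^2), 7 * 64 * sum(map^2), tolerance = 1e-9)
  }
})

test_that("surrogate baseline is exchangeable and unbiased", {
  set.seed(10)
  map <- matrix(stats::rnorm(7 * 128), 7, 128)
  ex <- surrogate_baseline(map, 256, exhaustive = TRUE)
  # permutation-group symmetry: forward and backward means identical
  expect_identical(ex$fw_ss, ex$bw_ss)
  # exhaustive mode is deterministic
  expect_identical(ex, surrogate_baseline(map, 256, exhaustive = TRUE))
  # random sampling converges to the exhaustive value (log scale: shuffle
  # aggregation is geometric)
  S <- 500
  ss <- surrogate_baseline(map, 256, n_shuffles = S, seed = 77)
  Tfft <- t(stats::mvfft(t(map)))
  sel <- twaves:::.bin_select(128, 256, c(2, 45))
  Wn <- twaves:::.spatial_dft_matrix(7)
  q <- twaves:::.quadrant_rows(7)
  perms <- twaves:::.all_perms(7)
  lvals <- log(t(apply(perms, 1, function(p)
    twaves:::.colmax_rows(Mod(Wn %*% Tfft[p, sel$idx])^2, q$neg))))
  sem <- apply(lvals, 2, stats::sd) / sqrt(S)
  expect_true(all(abs(log(ss$fw_ss) - log(ex$fw_ss)) < 4 * sem))
  expect_lt(abs(mean(log(ss$fw_ss) - log(ex$fw_ss))), 2 * mean(sem))
  # seeded draw is reproducible
  expect_identical(ss, surrogate_baseline(map, 256, n_shuffles = S, seed = 77))
})

test_that("dB conversion is the stated ratio formula", {
  expect_equal(waves_db(1, 1), 0)
  expect_equal(waves_db(2, 1), 10 * log10(2))
  expect_equal(waves_db(1, 2), -10 * log10(2))
  expect_error(waves_db(1, 0), "positive")
})

test_that("trial spectra detect a known forward wave and are deterministic", {
  set.seed(11)
  fs <- 256
  n <- 1280
  dat <- array(0, c(1, 7, n))
  noise <- generate_background(7, n, fs, exponent = 0, amplitude = 0.3, seed = 3)
  tt <- (0:(n - 1)) / fs
  wave <- t(sapply(0:6, function(k) cos(2 * pi * 10 * tt - k * pi / 4)))
  dat[1, , ] <- noise + wave
  ep <- epoch_set(dat, fs, paste0("ch", 1:7), data.frame(trial = 1))
  sp <- trial_wave_spectrum(ep, paste0("ch", 1:7), n_shuffles = 200, seed = 5)
  at10 <- sp[sp$freq == 10, ]
  expect_gt(at10$fw_db, 3)
  # a dominant forward wave suppresses the backward quadrant below its
  # surrogate (the shuffles redistribute forward energy into both quadrants),
  # so the backward dB goes clearly negative rather than to zero
  expect_lt(at10$bw_db, -3)
  expect_identical(sp, trial_wave_spectrum(ep, paste0("ch", 1:7),
                                           n_shuffles = 200, seed = 5))
})

test_that("forward dB grows monotonically with injected amplitude", {
  fs <- 256
  noise <- generate_background(7, 1280, fs, exponent = 0, amplitude = 1, seed = 21)
  amps <- c(0.2, 0.4, 0.8, 1.2, 1.6)
  tt <- (0:1279) / fs
  wave1 <- t(sapply(0:6, function(k) cos(2 * pi * 10 * tt - k * pi / 4)))
  vals <- vapply(amps, function(a) {
    dat <- array(0, c(1, 7, 1280))
    dat[1, , ] <- noise + a * wave1
    ep <- epoch_set(dat, fs, paste0("ch", 1:7), data.frame(trial = 1))
    sp <- trial_wave_spectrum(ep, paste0("ch", 1:7), f_range = c(8, 12),
                              n_shuffles = 50, seed = 6)
    sp$fw_db[sp$freq == 10]
  }, 0)
  expect_true(all(diff(vals) > -1e-9))
})

test_that("band table averages the right bins and assigns laterality", {
  lines <- tiny_line_set()
  freqs <- seq(2, 44, by = 2)
  md <- data.frame(subject = 1, trial = 1:2,
                   attended_side = c("left", "right"))
  base <- expand.grid(trial = 1:2, line_id = lines$line_id, freq = freqs,
                      stringsAsFactors = FALSE)
  base$subject <- 1
  # fw value encodes the frequency so band means are predictable
  base$fw_db <- base$freq
  base$bw_db <- 1
  bt <- band_table(base, md, lines)
  alpha_fw <- bt[bt$band == "alpha" & bt$direction == "FW", ]
  expect_true(all(alpha_fw$value_db == mean(c(8, 10, 12))))
  theta_fw <- bt[bt$band == "theta" & bt$direction == "FW", ]
  expect_true(all(theta_fw$value_db == mean(c(4, 6))))
  expect_true(all(bt$value_db[bt$direction == "BW"] == 1))
  # attend-left trial makes the right line contralateral: with one trial per
  # side, both lateral roles exist for the single pair
  expect_setequal(unique(bt$laterality), c("contra", "ipsi", "mid"))
  expect_error(band_table(base, md, lines,
                          bands = data.frame(band = "x", f_lo = 4.5,
                                             f_hi = 5.5)), "no frequency bins")
})

test_that("pair normalization is zero-sum and catches incomplete pairs", {
  tbl <- data.frame(subject = 1, pair_id = c("P1", "P1", "mid"),
                    laterality = c("contra", "ipsi", "mid"),
                    direction = "FW", band = "alpha",
                    value_db = c(1.0, 0.4, 0.7))
  out <- normalize_pairs(tbl)
  expect_equal(out$normalized_db[1:2], c(0.3, -0.3))
  expect_true(is.na(out$normalized_db[3]))
  expect_equal(sum(out$normalized_db[1:2]), 0)
  # equal pair values normalize to zero
  tbl2 <- tbl; tbl2$value_db <- c(0.5, 0.5, 0)
  expect_equal(normalize_pairs(tbl2)$normalized_db[1:2], c(0, 0))
  expect_error(normalize_pairs(tbl[-2, ]), "incomplete pair")
})

test_that("event-locked windows align to onset and skip edge cases", {
  lines <- tiny_line_set()
  fs <- 256
  n <- 1280
  chans <- line_set_electrodes(lines)
  dat <- array(stats::rnorm(3 * length(chans) * n, 0, 0.1),
               c(3, length(chans), n))
  # trial 1: strong forward wave only in the 500 ms after onset (1.5 s)
  tt <- (0:(n - 1)) / fs
  pm <- hemisphere_positions(lines)
  cmp <- wave_component(10, 3, pi / 4, onset = 1.5, offset = 2.0)
  sig <- matrix(dat[1, , ], length(chans), n)
  dat[1, , ] <- twaves:::.inject_wave_pos(sig, match(pm$label[pm$hemisphere == "left"], chans),
                                          pm$position[pm$hemisphere == "left"], cmp, fs)
  md <- data.frame(subject = 1, trial = 1:3,
                   attended_side = c("right", "right", "right"),
                   event_type = c("target", "target", "target"),
                   event_onset = c(1.5, 2.5, 0.2), # trial 3 too close to edge
                   outcome = c("hit", "miss", "hit"))
  ep <- epoch_set(dat, fs, chans, md)
  el <- event_locked_waves(ep, lines, n_shuffles = 50, seed = 3,
                           map_offsets = numeric(0))
  expect_equal(el$n_skipped, 1)
  expect_equal(el$skipped_trials, 3)
  t1 <- el$table[el$table$trial == 1 & el$table$line_id == "L1", ]
  # the wave lives only in the post window (stimulus right -> left line contra)
  expect_gt(t1$fw_db[t1$window == "post"], t1$fw_db[t1$window == "pre"] + 1)
  expect_equal(unique(el$table$laterality[el$table$line_id == "L1"]), "contra")
})
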
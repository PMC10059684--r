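test_that("wavelet power scales quadratically and vanishes for silence", {
  fs <- 256; n <- 1280
  tt <- (0:(n - 1)) / fs
  dat <- array(0, c(3, 1, n))
  dat[1, 1, ] <- 1 * cos(2 * pi * 10 * tt)
  dat[2, 1, ] <- 2 * cos(2 * pi * 10 * tt)
  ep <- epoch_set(dat, fs, "Cz", data.frame(trial = 1:3))
  # exact grid frequency: amplitude A gives power A^2
  mp <- morlet_power(ep, freqs = 10)
  expect_equal(mp$power[1, 1, 1], 1, tolerance = 0.01)
  expect_equal(mp$power[2, 1, 1] / mp$power[1, 1, 1], 4, tolerance = 0.01)
  expect_equal(mp$power[3, 1, 1], 0)
  # default log grid peaks at the bin nearest 10 Hz
  mp2 <- morlet_power(ep)
  expect_equal(which.max(mp2$power[1, 1, ]), which.min(abs(mp2$freqs - 10)))
  expect_true(all(mp2$power >= 0))
  # wavelet longer than the epoch errors with the frequency
  short <- epoch_set(dat[, , 1:128, drop = FALSE], fs, "Cz",
                     data.frame(trial = 1:3))
  expect_error(morlet_power(short, freqs = 1), "1 Hz")
})

test_that("white-noise power tracks the analytic filter response", {
  set.seed(12)
  fs <- 256; n <- 2560
  n_ch <- 30
  dat <- array(stats::rnorm(n_ch * n), c(n_ch, 1, n))
  ep <- epoch_set(dat, fs, "Cz", data.frame(trial = 1:n_ch))
  mp <- morlet_power(ep, n_freqs = 10, f_range = c(2, 40))
  # expected power of unit-variance white noise through each wavelet =
  # sum(|kernel|^2), recomputed here from the same stated design
  cyc <- 1 + (20 - 1) * (log(mp$freqs) - log(2)) / (log(40) - log(2))
  expected <- vapply(seq_along(mp$freqs), function(j) {
    sg <- cyc[j] / (2 * pi * mp$freqs[j])
    h <- ceiling(3 * sg * fs)
    tt <- (-h:h) / fs
    env <- exp(-tt^2 / (2 * sg^2))
    sum(Mod(complex(modulus = env, argument = 2 * pi * mp$freqs[j] * tt) *
              2 / sum(env))^2)
  }, 0)
  got <- colMeans(matrix(mp$power[, 1, ], n_ch))
  expect_lt(max(abs(log(got / expected))), 0.25)
})

test_that("regional alpha table is faithful bookkeeping", {
  lines <- tiny_line_set()
  chans <- line_set_electrodes(lines)
  md <- data.frame(subject = 1, trial = 1:2,
                   attended_side = c("right", "right"))
  freqs <- c(9, 10, 11)
  pw <- array(1, c(2, length(chans), 3))
  pobj <- list(power = pw, freqs = freqs, channels = chans, trials = 1:2)
  tab <- alpha_table(pobj, lines, md)
  expect_true(all(tab$alpha_power == 1))
  expect_setequal(unique(tab$region), c("occipital", "frontal"))
  # double power on left-hemisphere channels; attend-right makes left contra
  lh <- twaves:::.label_hemisphere(chans) == "left"
  pw2 <- pw; pw2[, lh, ] <- 2
  tab2 <- alpha_table(list(power = pw2, freqs = freqs, channels = chans,
                           trials = 1:2), lines, md)
  con <- tab2[tab2$laterality == "contra", "alpha_power"]
  ips <- tab2[tab2$laterality == "ipsi", "alpha_power"]
  expect_true(all(con == 2) && all(ips == 1))
  expect_error(alpha_table(list(power = pw, freqs = c(20, 30), channels = chans,
                                trials = 1:2), lines, md), "alpha")
})

test_that("lateralization topography is zero under identical conditions and folds correctly", {
  chans <- c("O1", "O2", "Oz")
  md <- data.frame(trial = 1:4, attended_side = c("left", "left", "right", "right"))
  pw <- array(1, c(4, 3, 2))
  pobj <- list(power = pw, freqs = c(9, 11), channels = chans, trials = 1:4)
  topo <- lateralization_topography(pobj, md)
  expect_true(all(topo$diff == 0))
  # boost ipsilateral channels: attend-left boosts O1, attend-right boosts O2
  pw2 <- pw
  pw2[1:2, 1, ] <- 2 # O1 on attend-left
  pw2[3:4, 2, ] <- 2 # O2 on attend-right
  topo2 <- lateralization_topography(list(power = pw2, freqs = c(9, 11),
                                          channels = chans, trials = 1:4), md)
  expect_gt(topo2$diff[topo2$channel == "O1"], 0)
  expect_lt(topo2$diff[topo2$channel == "O2"], 0)
  expect_equal(topo2$diff[topo2$channel == "O1"],
               -topo2$diff[topo2$channel == "O2"])
  # folded midline = plain average of the two conditions
  expect_equal(topo2$folded[topo2$channel == "Oz"], 1)
  # simulator oracle: ipsilateral standing-alpha boost shows the expected sign
  cfg <- sim_config(n_subjects = 1, n_trials_per_side = 15, channels = "montage",
                    alpha_ipsi_gain = 1.6, band_profile = FALSE,
                    event_rate = 0, eog_artifact_rate = 0, seed = 8)
  ep <- simulate_subject(cfg, 1, subject_seed = 13)$epochs
  agrid <- exp(seq(log(1), log(45), length.out = 30))
  mp <- morlet_power(ep, freqs = agrid[agrid >= 8 & agrid <= 12])
  topo3 <- lateralization_topography(mp, ep$metadata)
  lh <- twaves:::.label_hemisphere(topo3$channel)
  # attend-left boosts the left hemisphere: left diffs positive, right negative
  expect_gt(mean(topo3$diff[lh == "left"]), 0)
  expect_lt(mean(topo3$diff[lh == "right"]), 0)
})
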
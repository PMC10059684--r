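# Independent oracles used across tests. These deliberately avoid the
# package's own FFT/quadrature code paths.

# Brute-force 2D DFT by definition: F[ks, kt] = sum_e sum_t map[e,t] *
# exp(-2i*pi*(ks*e/n_e + kt*t/W)), evaluated cell by cell. Returns forward
# and backward quadrant maxima over the same bins as fft2d_directional.
oracle_fft2d <- function(map, fs, f_range = c(2, 45)) {
  n_e <- nrow(map); W <- ncol(map)
  freqs <- (0:(W - 1)) * fs / W
  kt_sel <- which(freqs >= f_range[1] & freqs <= min(f_range[2], fs / 2)) - 1L
  E <- matrix(0:(n_e - 1), n_e, W)
  Tt <- matrix(0:(W - 1), n_e, W, byrow = TRUE)
  cell <- function(ks, kt) {
    ph <- -2i * pi * (ks * E / n_e + kt * Tt / W)
    abs(sum(map * exp(ph)))^2 # quadrant power
  }
  half <- floor((n_e - 1) / 2)
  ks_pos <- 1:half
  ks_neg <- (n_e - half):(n_e - 1)
  fw <- bw <- numeric(length(kt_sel))
  fw_arg <- bw_arg <- integer(length(kt_sel))
  for (i in seq_along(kt_sel)) {
    vn <- vapply(ks_neg, cell, 0, kt = kt_sel[i])
    vp <- vapply(ks_pos, cell, 0, kt = kt_sel[i])
    fw[i] <- max(vn); fw_arg[i] <- ks_neg[which.max(vn)]
    bw[i] <- max(vp); bw_arg[i] <- ks_pos[which.max(vp)]
  }
  data.frame(freq = freqs[kt_sel + 1], fw_raw = fw, bw_raw = bw,
             fw_argmax = fw_arg, bw_argmax = bw_arg)
}

# argmax bins of the package's quadrant maxima, for the bit-level location
# comparison against the oracle
pkg_fft2d_argmax <- function(map, fs, f_range = c(2, 45)) {
  n_e <- nrow(map); W <- ncol(map)
  Tfft <- t(stats::mvfft(t(map)))
  freqs <- (0:(W - 1)) * fs / W
  sel <- which(freqs >= f_range[1] & freqs <= min(f_range[2], fs / 2))
  Wn <- twaves:::.spatial_dft_matrix(n_e)
  q <- twaves:::.quadrant_rows(n_e)
  A_fw <- Mod(Wn %*% Tfft[, sel, drop = FALSE])^2
  A_bw <- Mod(Wn %*% Tfft[n_e:1, sel, drop = FALSE])^2
  list(fw = apply(A_fw[q$neg, , drop = FALSE], 2, which.max),
       bw = apply(A_bw[q$neg, , drop = FALSE], 2, which.max))
}

# Riemann-sum JZS correlation Bayes factor (substitution g = u/(1-u))
oracle_jzs_cor <- function(r, n, K = 2e5) {
  u <- (seq_len(K) - 0.5) / K
  g <- u / (1 - u)
  lf <- (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g) -
    1.5 * log(g) - n / (2 * g)
  sqrt(n / 2) / gamma(0.5) * sum(exp(lf) / (1 - u)^2) / K
}

# closed-form chi-square upper tail for df = 4
oracle_chisq4_sf <- function(T) (1 + T / 2) * exp(-T / 2)

# mean periodogram over channels and log-log slope over a frequency band
psd_slope <- function(x, fs, f_lo = 2, f_hi = 45) {
  n <- ncol(x)
  P <- abs(stats::mvfft(t(x)))^2 / n
  freqs <- (0:(n - 1)) * fs / n
  keep <- freqs >= f_lo & freqs <= f_hi
  m <- rowMeans(P)[keep]
  unname(stats::coef(stats::lm(log10(m) ~ log10(freqs[keep])))[2])
}

# repeated-measures interaction F via the per-subject contrast: for a 2x2
# within design (averaging any further factors first), F = t^2 of the
# interaction contrast
oracle_rm_interaction_F <- function(d, dv, f1, f2, subject = "subject") {
  agg <- stats::aggregate(d[[dv]],
                          list(s = d[[subject]], a = d[[f1]], b = d[[f2]]), mean)
  cs <- sapply(split(agg, agg$s), function(g) {
    g <- g[order(g$a, g$b), ]
    g$x[1] - g$x[2] - g$x[3] + g$x[4]
  })
  n <- length(cs)
  (mean(cs) / (stats::sd(cs) / sqrt(n)))^2
}

# small deterministic line set (one pair + midline) for fast unit tests
tiny_line_set <- function() {
  line_set(data.frame(
    line_id = c("mid", "L1", "R1"),
    hemisphere = c("mid", "left", "right"),
    pair_id = c(NA, "P1", "P1"),
    e1 = c("Oz", "O1", "O2"), e2 = c("POz", "PO3", "PO4"),
    e3 = c("Pz", "P1", "P2"), e4 = c("CPz", "CP1", "CP2"),
    e5 = c("Cz", "C1", "C2"), e6 = c("FCz", "FC1", "FC2"),
    e7 = c("Fz", "F1", "F2"), stringsAsFactors = FALSE))
}

# closed-form plane-wave space-time map: rows occipital -> frontal,
# positive step = forward
plane_wave_map <- function(f, step, fs = 256, W = 128, n_e = 7, phase = 0,
                           amplitude = 1) {
  tt <- (0:(W - 1)) / fs
  t(sapply(0:(n_e - 1), function(k)
    amplitude * cos(2 * pi * f * tt - k * step + phase)))
}
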
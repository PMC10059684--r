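test_that("Fisher combination matches its formula and an independent oracle", {
  f1 <- fisher_combine(c(1, 1, 1))
  expect_equal(f1$T, 0)
  expect_equal(f1$p_combined, 1)
  f2 <- fisher_combine(c(0.05, 0.05))
  expect_equal(f2$T, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(f2$T, 11.98293, tolerance = 1e-5)
  expect_equal(f2$df, 4)
  # closed-form chi-square(4) upper tail as the oracle
  expect_equal(f2$p_combined, oracle_chisq4_sf(f2$T), tolerance = 1e-10)
  expect_error(fisher_combine(c(0.5, 0)), "floor")
  expect_error(fisher_combine(numeric(0)), "no p values")
})

test_that("Fisher method is permutation-invariant, monotone, and calibrated", {
  p <- c(0.3, 0.02, 0.77, 0.5)
  expect_equal(fisher_combine(p)$p_combined,
               fisher_combine(rev(p))$p_combined)
  expect_lt(fisher_combine(c(0.01, 0.5))$p_combined,
            fisher_combine(c(0.05, 0.5))$p_combined)
  # probability integral transform: combined p uniform under the null
  set.seed(13)
  ps <- replicate(2000, fisher_combine(stats::runif(16))$p_combined)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("JZS correlation Bayes factor agrees with the Riemann oracle", {
  grid <- expand.grid(r = c(0, 0.3, 0.6, 0.9), n = c(10, 20, 50))
  for (i in seq_len(nrow(grid))) {
    bf <- jzs_cor_bf(grid$r[i], grid$n[i])
    orc <- oracle_jzs_cor(grid$r[i], grid$n[i])
    expect_lt(abs(bf / orc - 1), 0.01)
  }
  # monotone in |r| at fixed n; diverges as |r| -> 1
  bfs <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 0.95), jzs_cor_bf, 0, n = 20)
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_cor_bf(1, 10), Inf)
  expect_equal(jzs_cor_bf(-0.5, 25), jzs_cor_bf(0.5, 25), tolerance = 1e-8)
})

test_that("pearson_bf handles the exact and the null case", {
  x <- 1:10
  res <- pearson_bf(x, x + 0)
  expect_equal(res$r, 1)
  expect_equal(res$bf10, Inf)
  expect_error(pearson_bf(x, rep(1, 10)), "variance")
  expect_error(pearson_bf(1:3, 2:4), "n >= 4")
  # independent normals: median BF below 1 (evidence for the null)
  set.seed(14)
  bfs <- replicate(300, pearson_bf(stats::rnorm(16), stats::rnorm(16))$bf10)
  expect_lt(stats::median(bfs), 1)
})

test_that("one-sample Bayes-factor t test behaves sensibly", {
  set.seed(15)
  null_bf <- bf_ttest_onesample(stats::rnorm(20, 0, 1))$bf10
  eff_bf <- bf_ttest_onesample(stats::rnorm(20, 1.2, 1))$bf10
  expect_gt(eff_bf, 10)
  expect_lt(null_bf, 2)
  # BF increases with |t| at fixed n
  xs <- seq(0, 1, by = 0.25)
  bfs <- vapply(xs, function(m) bf_ttest_onesample(seq(-1, 1, length.out = 15) + m)$bf10, 0)
  expect_true(all(diff(bfs) > 0))
})

test_that("repeated-measures ANOVA recovers constructed contrasts", {
  # deterministic cell means: contra-FW and ipsi-BW boosted, zero elsewhere;
  # a pure DIRECTION x LATERALITY interaction with no main effects
  set.seed(16)
  d <- expand.grid(subject = 1:10, direction = c("FW", "BW"),
                   laterality = c("contra", "ipsi"), line = 1:5)
  d$y <- 0.5 * ifelse((d$direction == "FW") == (d$laterality == "contra"), 1, -1)
  d$y <- d$y + stats::rnorm(nrow(d), 0, 0.2)
  an <- mixed_anova(d, "y", c("direction", "line", "laterality"),
                    compute_bf = TRUE)
  ia <- an[an$term == "direction x laterality", ]
  expect_lt(ia$p, 1e-4)
  expect_gt(ia$bf10, 10)
  expect_gt(min(an$p[an$term %in% c("direction", "laterality")]), 0.01)
  # F of the interaction equals the squared t of the per-subject contrast
  expect_equal(ia$F, oracle_rm_interaction_F(d, "y", "direction", "laterality"),
               tolerance = 1e-8)
  # each term is tested in its own subject-by-term stratum
  expect_equal(ia$df2, 9)
  expect_equal(an$df2[an$term == "direction x line"], 9 * 4)
  # missing cells are refused
  expect_error(mixed_anova(d[-(1:20), ], "y",
                           c("direction", "line", "laterality")), "balanced")
})

test_that("ANOVA interaction p values are uniform under the null", {
  set.seed(17)
  ps <- replicate(400, {
    d <- expand.grid(subject = 1:8, direction = c("FW", "BW"),
                     laterality = c("contra", "ipsi"))
    d$y <- stats::rnorm(nrow(d))
    an <- mixed_anova(d, "y", c("direction", "laterality"), compute_bf = FALSE)
    an$p[an$term == "direction x laterality"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # type-I level at alpha = 0.05 within the binomial band
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.025)
})

test_that("trial-by-trial correlation layer wires conditions correctly", {
  # synthetic per-trial tables with a known positive link in BW-contra only
  set.seed(18)
  waves <- NULL; power <- NULL
  for (s in 1:8) {
    n <- 40
    z <- stats::rnorm(n)
    for (lat in c("contra", "ipsi")) {
      for (dir in c("FW", "BW")) {
        val <- stats::rnorm(n, 0, 1)
        if (dir == "BW" && lat == "contra") val <- val + 1.2 * z
        waves <- rbind(waves, data.frame(subject = s, trial = 1:n,
                                         laterality = lat, direction = dir,
                                         alpha_db = val))
      }
      for (reg in c("occipital", "frontal")) {
        power <- rbind(power, data.frame(subject = s, trial = 1:n,
                                         region = reg, laterality = lat,
                                         alpha_power = stats::rnorm(n, 0, 1) + z))
      }
    }
  }
  res <- trialwise_wave_power_correlation(waves, power)
  bc <- res$by_condition
  hit <- bc[bc$direction == "BW" & bc$laterality == "contra", ]
  expect_true(all(hit$p_combined < 1e-6))
  expect_true(all(hit$mean_r > 0.3))
  expect_true(all(hit$bf10_r > 10))
  others <- bc[!(bc$direction == "BW" & bc$laterality == "contra") &
                 bc$laterality != "lateralization", ]
  expect_true(all(abs(others$mean_r) < 0.2))
  # per-subject rows carry the full grid
  expect_equal(nrow(res$by_subject), 8 * 12)
})
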
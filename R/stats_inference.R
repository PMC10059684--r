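#' Repeated-measures ANOVA with approximate Bayes factors
#'
#' Classical within-subject ANOVA (subjects as the random factor) over fully
#' crossed within factors, via `stats::aov` error strata: each term is tested
#' against its own subject-by-term stratum. Partial eta-squared is
#' SS_term / (SS_term + SS_error) within the stratum. `bf10` is a BIC
#' approximation - exp((BIC_without - BIC_with)/2) from maximum-likelihood
#' random-intercept models (lme4) with and without the term (higher-order
#' terms containing it are removed alongside, respecting marginality). It is
#' labeled approximate: it is not a model-averaged Bayesian ANOVA, but it
#' preserves effect ordering in calibration checks.
#'
#' @param data data.frame in long format, one or more rows per subject x cell
#'   (replicates are averaged).
#' @param dv name of the response column.
#' @param within character vector of within-subject factor columns.
#' @param subject name of the subject column.
#' @param compute_bf compute the BIC-approximate Bayes factors (needs a few
#'   lme4 fits; disable in tight Monte-Carlo loops).
#' @return data.frame with one row per term: `term`, `df1`, `df2`, `F`, `p`,
#'   `peta2`, `bf10` (NA when `compute_bf = FALSE`).
#' @export
mixed_anova <- function(data, dv, within, subject = "subject",
                        compute_bf = TRUE) {
  d <- data[c(subject, within, dv)]
  names(d) <- c(".subj", paste0(".w", seq_along(within)), ".y")
  if (anyNA(d$.y)) .stopf("response contains NA")
  for (v in c(".subj", paste0(".w", seq_along(within)))) d[[v]] <- factor(d[[v]])
  agg <- stats::aggregate(.y ~ ., d, mean)
  if (nlevels(agg$.subj) < 2) .stopf("need at least 2 subjects")
  cells <- table(interaction(agg[paste0(".w", seq_along(within))]), agg$.subj)
  if (any(cells != 1)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    .stopf("design is not complete/balanced: %d missing subject-cells",
           sum(cells == 0))
  }
  wterms <- paste0(".w", seq_along(within))
  fixed <- paste(wterms, collapse = " * ")
  f <- stats::as.formula(sprintf(".y ~ %s + Error(.subj/(%s))", fixed, fixed))
  fit <- stats::aov(f, data = agg)
  sm <- summary(fit)
  out <- NULL
  for (stratum in sm) {
    tb <- stratum[[1]]
    terms <- trimws(rownames(tb))
    resid <- terms == "Residuals"
    if (!any(!resid) || !any(resid)) next
    ssr <- tb[resid, "Sum Sq"]
    dfr <- tb[resid, "Df"]
    for (i in which(!resid)) {
      out <- rbind(out, data.frame(
        term = terms[i], df1 = tb[i, "Df"], df2 = dfr,
        F = tb[i, "F value"], p = tb[i, "Pr(>F)"],
        peta2 = tb[i, "Sum Sq"] / (tb[i, "Sum Sq"] + ssr),
        stringsAsFactors = FALSE))
    }
  }
  # map .w names back
  for (i in seq_along(within))
    out$term <- gsub(paste0(".w", i), within[i], out$term, fixed = TRUE)
  out$term <- gsub(":", " x ", out$term)
  out$bf10 <- NA_real_
  if (compute_bf) {
    all_terms <- attr(stats::terms(stats::as.formula(paste("~", fixed))), "term.labels")
    full_f <- stats::as.formula(paste(".y ~", paste(all_terms, collapse = "+"),
                                      "+ (1 | .subj)"))
    full <- suppressMessages(lme4::lmer(full_f, data = agg, REML = FALSE))
    bic_full <- stats::BIC(full)
    for (i in seq_len(nrow(out))) {
      tlab <- gsub(" x ", ":", out$term[i])
      for (j in seq_along(within)) tlab <- gsub(within[j], paste0(".w", j), tlab, fixed = TRUE)
      parts_t <- strsplit(tlab, ":")[[1]]
      keep <- all_terms[!vapply(all_terms, function(a) {
        pa <- strsplit(a, ":")[[1]]
        all(parts_t %in% pa)
      }, logical(1))]
      red_f <- if (length(keep))
        stats::as.formula(paste(".y ~", paste(keep, collapse = "+"), "+ (1 | .subj)"))
      else stats::as.formula(".y ~ 1 + (1 | .subj)")
      red <- suppressMessages(lme4::lmer(red_f, data = agg, REML = FALSE))
      out$bf10[i] <- exp((stats::BIC(red) - bic_full) / 2)
    }
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a JZS default-prior Bayes factor
#'
#' The Bayes factor for the presence of a correlation under the
#' Jeffreys-Zellner-Siow default prior, evaluated by adaptive quadrature of
#' \deqn{BF_{10} = \sqrt{n/2}/\Gamma(1/2) \int_0^\infty (1+g)^{(n-2)/2}
#'   (1+(1-r^2)g)^{-(n-1)/2} g^{-3/2} e^{-n/(2g)} dg.}
#'
#' @param x,y numeric vectors (n >= 4, finite, non-constant).
#' @return list with `r`, `n`, `p` (two-sided classical test), `bf10`.
#' @export
pearson_bf <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) .stopf("need paired vectors, n >= 4")
  if (!all(is.finite(x)) || !all(is.finite(y))) .stopf("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) .stopf("zero-variance input")
  ct <- stats::cor.test(x, y)
  r <- unname(ct$estimate)
  if (1 - abs(r) < 1e-14) r <- sign(r) # exactly collinear up to rounding
  list(r = r, n = length(x), p = ct$p.value, bf10 = jzs_cor_bf(r, length(x)))
}

#' @rdname pearson_bf
#' @param r observed Pearson coefficient; `n` sample size.
#' @export
jzs_cor_bf <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 4)
  if (abs(r) == 1) return(Inf)
  logf <- function(g) (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g) -
    1.5 * log(g) - n / (2 * g)
  opt <- stats::optimize(function(lg) logf(exp(lg)), c(-20, 20), maximum = TRUE)
  shift <- opt$objective
  int <- stats::integrate(function(g) exp(logf(g) - shift), 0, Inf,
                          rel.tol = 1e-10, subdivisions = 500L)
  sqrt(n / 2) / gamma(0.5) * exp(shift) * int$value
}

#' One-sample JZS Bayes-factor t test
#'
#' Default-prior (Cauchy scale `rscale`) Bayes factor for a one-sample mean
#' against `mu`, by quadrature over the mixing parameter g with
#' g ~ InverseGamma(1/2, rscale^2/2).
#'
#' @param x numeric vector (n >= 2).
#' @param mu null value.
#' @param rscale Cauchy prior scale (default sqrt(2)/2, the conventional
#'   medium scale).
#' @return list with `t`, `df`, `p`, `bf10`.
#' @export
bf_ttest_onesample <- function(x, mu = 0, rscale = sqrt(2) / 2) {
  n <- length(x)
  stopifnot(n >= 2)
  tt <- stats::t.test(x, mu = mu)
  t <- unname(tt$statistic)
  nu <- n - 1
  log_h0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  logf <- function(g) -0.5 * log1p(n * g) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) +
    0.5 * log(rscale^2 / 2) - lgamma(0.5) - 1.5 * log(g) - rscale^2 / (2 * g)
  opt <- stats::optimize(function(lg) logf(exp(lg)), c(-25, 25), maximum = TRUE)
  shift <- opt$objective
  int <- stats::integrate(function(g) exp(logf(g) - shift), 0, Inf,
                          rel.tol = 1e-10, subdivisions = 500L)
  list(t = t, df = nu, p = tt$p.value,
       bf10 = exp(shift + log(int$value) - log_h0))
}

#' Fisher's combined probability test
#'
#' T = -2 * sum(ln p_i), compared against the upper tail of a chi-square
#' distribution with 2N degrees of freedom. p values must lie in (0, 1];
#' exact zeros are rejected (the caller should floor them, e.g. at 1e-300).
#'
#' @param p_values vector of independent p values.
#' @return list with `p_values`, `N`, `T`, `df`, `p_combined`.
#' @export
fisher_combine <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) .stopf("no p values supplied")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    .stopf("p values must lie in (0, 1]; floor exact zeros before combining")
  T <- -2 * sum(log(p))
  N <- length(p)
  list(p_values = p, N = N, T = T, df = 2 * N,
       p_combined = stats::pchisq(T, df = 2 * N, lower.tail = FALSE))
}

#' Trial-by-trial wave-power correlation analysis
#'
#' For every subject and condition, correlates single-trial alpha-band wave
#' amount (dB) with single-trial regional alpha power; conditions are the
#' direction x region x laterality grid (wave and power laterality matched)
#' plus a lateralization condition per direction x region in which both
#' variables are contra-minus-ipsi differences. Per condition, subjects'
#' p values are Fisher-combined (floored at 1e-300 before the log) and the
#' distribution of correlation coefficients is tested against zero with a
#' default-prior Bayes-factor t test on Fisher-z-transformed r.
#'
#' @param waves per-trial wave values from [trial_band_waves()].
#' @param power a [alpha_table()] data.frame.
#' @param min_trials minimum trials per subject to enter (default 10).
#' @return list with `by_subject` (subject x condition r and p) and
#'   `by_condition` (mean r, combined p, t-test BF).
#' @export
trialwise_wave_power_correlation <- function(waves, power, min_trials = 10) {
  wkey <- paste(waves$subject, waves$trial)
  pkey <- paste(power$subject, power$trial)
  common <- intersect(unique(wkey), unique(pkey))
  if (length(common) == 0) .stopf("no common (subject, trial) rows")
  conds <- expand.grid(direction = c("FW", "BW"),
                       region = c("occipital", "frontal"),
                       laterality = c("contra", "ipsi", "lateralization"),
                       stringsAsFactors = FALSE)
  rows <- NULL
  for (s in unique(waves$subject)) {
    ws <- waves[waves$subject == s, ]
    ps <- power[power$subject == s, ]
    for (ci in seq_len(nrow(conds))) {
      cc <- conds[ci, ]
      if (cc$laterality == "lateralization") {
        wc <- ws[ws$direction == cc$direction & ws$laterality == "contra", ]
        wi <- ws[ws$direction == cc$direction & ws$laterality == "ipsi", ]
        pc <- ps[ps$region == cc$region & ps$laterality == "contra", ]
        pi_ <- ps[ps$region == cc$region & ps$laterality == "ipsi", ]
        tr <- Reduce(intersect, list(wc$trial, wi$trial, pc$trial, pi_$trial))
        if (length(tr) < min_trials) next
        xv <- wc$alpha_db[match(tr, wc$trial)] - wi$alpha_db[match(tr, wi$trial)]
        yv <- pc$alpha_power[match(tr, pc$trial)] - pi_$alpha_power[match(tr, pi_$trial)]
      } else {
        wv <- ws[ws$direction == cc$direction & ws$laterality == cc$laterality, ]
        pv <- ps[ps$region == cc$region & ps$laterality == cc$laterality, ]
        tr <- intersect(wv$trial, pv$trial)
        if (length(tr) < min_trials) next
        xv <- wv$alpha_db[match(tr, wv$trial)]
        yv <- pv$alpha_power[match(tr, pv$trial)]
      }
      ct <- stats::cor.test(xv, yv)
      rows <- rbind(rows, data.frame(
        subject = s, direction = cc$direction, region = cc$region,
        laterality = cc$laterality, n = length(tr),
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) .stopf("no subject reached min_trials")
  agg <- NULL
  for (k in unique(paste(rows$direction, rows$region, rows$laterality))) {
    sub <- rows[paste(rows$direction, rows$region, rows$laterality) == k, ]
    fc <- fisher_combine(pmax(sub$p, 1e-300))
    bt <- if (nrow(sub) >= 2) bf_ttest_onesample(atanh(pmin(pmax(sub$r, -1 + 1e-12),
                                                            1 - 1e-12)))
    else list(bf10 = NA_real_, p = NA_real_)
    agg <- rbind(agg, data.frame(
      direction = sub$direction[1], region = sub$region[1],
      laterality = sub$laterality[1], n_subjects = nrow(sub),
      mean_r = mean(sub$r), p_combined = fc$p_combined, T = fc$T,
      bf10_r = bt$bf10, stringsAsFactors = FALSE))
  }
  list(by_subject = rows, by_condition = agg)
}
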
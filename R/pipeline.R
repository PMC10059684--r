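#' Spectral profile of forward and backward waves
#'
#' The resting wave profile: FW/BW dB spectra (2-45 Hz) averaged over the
#' trials in which no target or distractor appeared, reported for the midline
#' and for the hemisphere-averaged contralateral and ipsilateral lateral
#' lines.
#'
#' @param spectra long spectra from [wave_spectra()] (no-event trials).
#' @param metadata epoch metadata.
#' @param lines the [line_set()].
#' @return data.frame `group` (midline/contra/ipsi), `freq`, `direction`,
#'   `db`.
#' @export
spectral_profile <- function(spectra, metadata, lines) {
  key <- paste(metadata$subject, metadata$trial)
  side <- metadata$attended_side[match(paste(spectra$subject, spectra$trial), key)]
  hemi <- lines$hemisphere[match(spectra$line_id, lines$line_id)]
  lat <- .laterality(hemi, side)
  grp <- ifelse(lat == "mid", "midline", lat)
  long <- rbind(
    data.frame(group = grp, freq = spectra$freq, direction = "FW", db = spectra$fw_db),
    data.frame(group = grp, freq = spectra$freq, direction = "BW", db = spectra$bw_db))
  out <- stats::aggregate(db ~ group + freq + direction, long, mean)
  out[order(out$direction, out$group, out$freq), ]
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Orchestrates simulate -> waves -> power -> statistics, per subject to
#' bound memory, and returns (optionally writes) figure-ready tidy tables:
#' the resting FW/BW spectral profile, the normalized band-wave table with
#' its DIRECTION x LINE x LATERALITY ANOVA (alpha band), between-subject and
#' trial-by-trial wave-power correlations, and the event-locked analysis.
#' The block analyses use only trials without a target or distractor; the
#' event analysis only trials with one. A JSON manifest (config echo,
#' version, per-stage counts, output hashes, timing) makes simulated runs
#' exactly reproducible.
#'
#' @param config a [sim_config()].
#' @param lines a [line_set()].
#' @param analyses subset of `"spectral_profile"`, `"block"`, `"correlation"`,
#'   `"event"`.
#' @param out_dir directory for CSV/JSON outputs (NULL = return only).
#' @param n_shuffles surrogate permutations per window.
#' @param f_range temporal frequency range for spectra.
#' @param reject_eog apply EOG-based trial rejection before analysis.
#' @param min_trials minimum no-event trials per subject for the trial-by-trial
#'   correlation analysis.
#' @param compute_bf compute approximate Bayes factors in the ANOVAs.
#' @return list of result tables plus `manifest`.
#' @export
run_pipeline <- function(config, lines = default_line_set(),
                         analyses = c("spectral_profile", "block",
                                      "correlation", "event"),
                         out_dir = NULL, n_shuffles = 100,
                         f_range = c(2, 45), reject_eog = TRUE,
                         compute_bf = TRUE, min_trials = 10) {
  t0 <- Sys.time()
  if (length(analyses) == 0) .stopf("at least one analysis is required")
  analyses <- match.arg(analyses, several.ok = TRUE)
  if ("event" %in% analyses && config$event_rate == 0)
    .stopf("event analysis requested but the configuration produces no events")
  seeds <- .with_seed(config$seed,
                      sample.int(.Machine$integer.max - 1, config$n_subjects + 1))
  spectra <- NULL; waves_tr <- NULL; pow_tab <- NULL; ev_tab <- NULL
  ev_map <- NULL; ev_skipped <- 0
  n_rej <- integer(config$n_subjects)
  need_block_spectra <- any(c("spectral_profile", "block", "correlation") %in% analyses)
  for (s in seq_len(config$n_subjects)) {
    sim <- simulate_subject(config, s, lines, subject_seed = seeds[s])
    ep <- sim$epochs
    ep$metadata$trial <- ep$metadata$trial + (s - 1) * 10^ceiling(log10(n_trials(ep) + 1))
    if (reject_eog) {
      ep2 <- reject_eog_trials(ep)
      n_rej[s] <- attr(ep2, "n_rejected")
      ep <- ep2
    }
    md <- ep$metadata
    noev <- which(md$event_type == "none")
    if (need_block_spectra && length(noev)) {
      sp <- wave_spectra(ep, lines, trials = noev, f_range = f_range,
                         n_shuffles = n_shuffles, seed = seeds[s])
      spectra <- rbind(spectra, cbind(sp, row.names = NULL))
      if ("correlation" %in% analyses) {
        waves_tr <- rbind(waves_tr, trial_band_waves(sp, md, lines))
        pw <- morlet_power(ep, channels = intersect(region_electrodes(lines),
                                                    ep$channels),
                           trials = noev)
        pow_tab <- rbind(pow_tab, alpha_table(pw, lines, md))
      }
    }
    if ("event" %in% analyses) {
      evs <- which(md$event_type %in% c("target", "distractor"))
      if (length(evs)) {
        el <- event_locked_waves(ep[evs], lines, n_shuffles = n_shuffles,
                                 f_range = c(8, 12), seed = seeds[s] %% 10^8)
        ev_tab <- rbind(ev_tab, el$table)
        ev_map <- rbind(ev_map, el$map)
        ev_skipped <- ev_skipped + el$n_skipped
      }
    }
    md_all <- if (s == 1) md else rbind(md_all, md)
  }
  res <- list()
  if ("spectral_profile" %in% analyses)
    res$spectral_profile <- spectral_profile(spectra, md_all, lines)
  if ("block" %in% analyses) {
    bt <- normalize_pairs(band_table(spectra, md_all, lines))
    res$band_table <- bt
    alpha_lat <- bt[bt$band == "alpha" & bt$laterality != "mid", ]
    alpha_lat$line <- sub("^P", "", alpha_lat$pair_id)
    res$block_anova <- mixed_anova(alpha_lat, dv = "normalized_db",
                                   within = c("direction", "line", "laterality"),
                                   compute_bf = compute_bf)
  }
  if ("correlation" %in% analyses) {
    res$trialwise <- trialwise_wave_power_correlation(waves_tr, pow_tab,
                                                      min_trials = min_trials)
    # between-subject correlations on subject-mean values (Table-1 style grid)
    bt_w <- stats::aggregate(alpha_db ~ subject + laterality + direction,
                             waves_tr, mean)
    bt_p <- stats::aggregate(alpha_power ~ subject + region + laterality,
                             pow_tab, mean)
    grid <- expand.grid(direction = c("FW", "BW"),
                        wave_lat = c("contra", "ipsi"),
                        region = c("occipital", "frontal"),
                        power_lat = c("contra", "ipsi"),
                        stringsAsFactors = FALSE)
    bs <- NULL
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      x <- bt_w[bt_w$direction == g$direction & bt_w$laterality == g$wave_lat, ]
      y <- bt_p[bt_p$region == g$region & bt_p$laterality == g$power_lat, ]
      subj <- intersect(x$subject, y$subject)
      if (length(subj) < 4) next
      pb <- pearson_bf(x$alpha_db[match(subj, x$subject)],
                       y$alpha_power[match(subj, y$subject)])
      bs <- rbind(bs, cbind(g, data.frame(n = pb$n, r = pb$r, p = pb$p,
                                          bf10 = pb$bf10)))
    }
    res$between_subject <- bs
  }
  if ("event" %in% analyses) {
    res$event_table <- ev_tab
    res$event_map <- ev_map
    res$event_skipped <- ev_skipped
    ebt <- event_band_table(ev_tab, lines, by = "event_type")
    contra <- ebt[ebt$laterality == "contra" & ebt$window == "post", ]
    res$event_anova <- tryCatch(
      mixed_anova(contra, dv = "normalized_db", within = c("direction", "cond"),
                  compute_bf = compute_bf),
      error = function(e) NULL)
    obt <- event_band_table(ev_tab, lines, by = "outcome")
    ocontra <- obt[obt$laterality == "contra" & obt$window == "post", ]
    res$outcome_anova <- tryCatch(
      mixed_anova(ocontra, dv = "normalized_db", within = c("direction", "cond"),
                  compute_bf = compute_bf),
      error = function(e) NULL)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("twaves")),
    config = unclass(config), analyses = analyses,
    n_shuffles = n_shuffles, f_range = f_range,
    n_trials_rejected = n_rej, event_trials_skipped = ev_skipped,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (nm in names(res)) {
      ob <- res[[nm]]
      if (is.data.frame(ob)) {
        fp <- file.path(out_dir, paste0(nm, ".csv"))
        utils::write.csv(ob, fp, row.names = FALSE)
        files <- c(files, fp)
      } else if (nm == "trialwise") {
        for (part in names(ob)) {
          fp <- file.path(out_dir, paste0("trialwise_", part, ".csv"))
          utils::write.csv(ob[[part]], fp, row.names = FALSE)
          files <- c(files, fp)
        }
      }
    }
    manifest$output_md5 <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  res$manifest <- manifest
  res
}
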
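#' Epoched multichannel EEG
#'
#' Container for a trials x channels x samples array with sampling rate,
#' channel labels, the epoch window relative to trial onset, and per-trial
#' metadata (`subject`, `trial`, `attended_side`, `event_type`, `event_onset`,
#' `outcome`). Trial metadata rows are in one-to-one correspondence with the
#' first array dimension.
#'
#' @param data numeric array `trials x channels x samples`.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel labels (length = dim 2).
#' @param metadata data.frame with one row per trial.
#' @param t_start epoch start in seconds relative to trial onset.
#' @param eog_channels labels of ocular channels (subset of `channels`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, channels, metadata, t_start = 0,
                      eog_channels = character(0)) {
  stopifnot(length(dim(data)) == 3, fs > 0)
  if (dim(data)[2] != length(channels)) .stopf("channel labels do not match data")
  if (anyDuplicated(channels)) .stopf("channel labels must be unique")
  if (nrow(metadata) != dim(data)[1]) .stopf("metadata rows must equal trial count")
  if (!all(eog_channels %in% channels)) .stopf("eog_channels must be in channels")
  if (is.null(metadata$trial)) metadata$trial <- seq_len(nrow(metadata))
  structure(list(data = data, fs = fs, channels = channels,
                 metadata = metadata, t_start = t_start,
                 eog_channels = eog_channels),
            class = "epoch_set")
}

#' @export
#' @method print epoch_set
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz (t0 = %g s)\n",
              d[1], d[2], d[3], x$fs, x$t_start))
  if (!is.null(x$metadata$subject))
    cat(sprintf("  subjects: %s\n", paste(unique(x$metadata$subject), collapse = ", ")))
  invisible(x)
}

#' @export
`[.epoch_set` <- function(x, i) {
  i <- seq_len(dim(x$data)[1])[i]
  epoch_set(x$data[i, , , drop = FALSE], x$fs, x$channels,
            x$metadata[i, , drop = FALSE], x$t_start, x$eog_channels)
}

#' Number of trials in an epoch set
#' @param x an `epoch_set`
#' @export
n_trials <- function(x) dim(x$data)[1]

# channels x samples matrix for one trial
.trial_matrix <- function(x, trial) {
  m <- x$data[trial, , , drop = FALSE]
  dim(m) <- dim(x$data)[2:3]
  rownames(m) <- x$channels
  m
}

# trials x 7 x samples array for one electrode line
.line_array <- function(x, labels) {
  idx <- match(labels, x$channels)
  if (anyNA(idx)) .stopf("channel label(s) not found: %s",
                         paste(labels[is.na(idx)], collapse = ", "))
  x$data[, idx, , drop = FALSE]
}

#' Combine epoch sets trial-wise
#' @param ... `epoch_set` objects sharing fs, channels and window.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "epoch_set")) xs <- xs[[1]]
  ref <- xs[[1]]
  for (x in xs[-1]) {
    if (!identical(x$channels, ref$channels) || x$fs != ref$fs ||
        x$t_start != ref$t_start)
      .stopf("epoch sets are not compatible")
  }
  dat <- do.call(abind3, lapply(xs, `[[`, "data"))
  md <- do.call(rbind, lapply(xs, `[[`, "metadata"))
  epoch_set(dat, ref$fs, ref$channels, md, ref$t_start, ref$eog_channels)
}

# rbind 3-d arrays along the first (trial) dimension
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1], 0))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Write / read an epoch set as plain-text CSV
#'
#' Two files are produced: `<stem>_meta.csv` (per-trial metadata plus fs,
#' window and channel list in a JSON sidecar) and `<stem>_data.csv`, the
#' signal in long trial/channel rows. Intended for small fixtures and
#' round-trip checks, not bulk storage.
#'
#' @param x an `epoch_set`; `stem` path stem without extension.
#' @export
write_epoch_set <- function(x, stem) {
  utils::write.csv(x$metadata, paste0(stem, "_meta.csv"), row.names = FALSE)
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  idx <- expand.grid(channel = x$channels, trial = seq_len(d[1]),
                     stringsAsFactors = FALSE)[, 2:1]
  utils::write.csv(cbind(idx, as.data.frame(flat)), paste0(stem, "_data.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(fs = x$fs, t_start = x$t_start, channels = x$channels,
                            eog_channels = x$eog_channels),
                       paste0(stem, "_attrs.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(stem) {
  meta <- utils::read.csv(paste0(stem, "_meta.csv"), stringsAsFactors = FALSE)
  attrs <- jsonlite::read_json(paste0(stem, "_attrs.json"), simplifyVector = TRUE)
  long <- utils::read.csv(paste0(stem, "_data.csv"), stringsAsFactors = FALSE)
  ns <- ncol(long) - 2
  nt <- nrow(meta); nc <- length(attrs$channels)
  dat <- aperm(array(t(as.matrix(long[, -(1:2)])), c(ns, nc, nt)), c(3, 2, 1))
  epoch_set(dat, attrs$fs, attrs$channels, meta, attrs$t_start,
            as.character(attrs$eog_channels))
}
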
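#' Electrode line sets
#'
#' A line set describes ordered occipito-frontal chains of 7 electrodes used
#' for the space-time wave analysis: one midline plus left/right homologous
#' pairs. The default set has 11 lines (5 per hemisphere and 1 midline) on a
#' BioSemi-64 style 10-20 montage; the midline is Oz, POz, Pz, CPz, Cz, FCz,
#' Fz. The lateral lines are a plausible symmetric reconstruction and ship as
#' an editable CSV (`inst/extdata/lines_biosemi64.csv`); outer lines overlap,
#' which is deliberate (the chains cover each hemisphere with overlapping
#' electrode choices).
#'
#' @param df data.frame with columns `line_id`, `hemisphere`
#'   (`left`/`right`/`mid`), `pair_id` (NA for the midline) and `e1`..`e7`,
#'   the electrode labels ordered occipital (`e1`) to frontal (`e7`).
#' @return An object of class `line_set` (a validated data.frame).
#' @export
line_set <- function(df) {
  need <- c("line_id", "hemisphere", "pair_id", paste0("e", 1:7))
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("line set is missing columns: %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$line_id)) .stopf("duplicated line_id in line set")
  if (!all(df$hemisphere %in% c("left", "right", "mid")))
    .stopf("hemisphere must be left/right/mid")
  if (sum(df$hemisphere == "mid") != 1) .stopf("line set must contain exactly one midline")
  lat <- df[df$hemisphere != "mid", ]
  for (p in unique(lat$pair_id)) {
    h <- sort(lat$hemisphere[lat$pair_id == p])
    if (!identical(h, c("left", "right")))
      .stopf("pair '%s' is incomplete: needs one left and one right line", p)
  }
  class(df) <- c("line_set", "data.frame")
  df
}

#' @rdname line_set
#' @export
default_line_set <- function() {
  path <- system.file("extdata", "lines_biosemi64.csv", package = "twaves")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  line_set(df)
}

#' @rdname line_set
#' @param path CSV file with the columns documented above.
#' @export
read_line_set <- function(path) {
  line_set(utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA"))
}

#' Electrode labels of one line, occipital to frontal
#'
#' @param lines a `line_set`
#' @param id a `line_id`
#' @return Character vector of 7 labels.
#' @export
line_electrodes <- function(lines, id) {
  i <- match(id, lines$line_id)
  if (is.na(i)) .stopf("unknown line_id '%s'", id)
  unname(unlist(lines[i, paste0("e", 1:7)]))
}

#' All electrode labels used by a line set
#' @inheritParams line_electrodes
#' @export
line_set_electrodes <- function(lines) {
  unique(unname(unlist(lines[, paste0("e", 1:7)])))
}

#' Mirror a 10-20 electrode label across the midline
#'
#' Odd-numbered labels are left-hemisphere, even right; `z` labels are on the
#' midline and map to themselves (fold fixed points).
#'
#' @param label character vector of 10-20 style labels (e.g. "PO3", "Fz").
#' @return The left/right homologous labels.
#' @export
mirror_label <- function(label) {
  vapply(label, function(l) {
    m <- regmatches(l, regexec("^([A-Za-z]+?)([0-9]+)$", l))[[1]]
    if (length(m) == 0) return(l) # z labels and anything non-numbered
    num <- as.integer(m[3])
    paste0(m[2], if (num %% 2 == 1) num + 1L else num - 1L)
  }, character(1), USE.NAMES = FALSE)
}

# Hemisphere of a 10-20 label: left / right / mid.
.label_hemisphere <- function(label) {
  vapply(label, function(l) {
    m <- regmatches(l, regexec("([0-9]+)$", l))[[1]]
    if (length(m) == 0) return("mid")
    if (as.integer(m[2]) %% 2 == 1) "left" else "right"
  }, character(1), USE.NAMES = FALSE)
}

# Laterality of a line hemisphere relative to an attended (or stimulus) side.
.laterality <- function(hemisphere, side) {
  ifelse(hemisphere == "mid", "mid", ifelse(hemisphere == side, "ipsi", "contra"))
}

#' Occipito-frontal position of each electrode in a line set
#'
#' Lines within a hemisphere overlap; a consistent line set places each
#' shared electrode at the same position (1 = most occipital .. 7 = most
#' frontal) in every line it belongs to, so a single traveling wave per
#' hemisphere induces a perfect plane wave along every line.
#'
#' @param lines a [line_set()]
#' @return data.frame `label`, `hemisphere`, `position`; errors if any
#'   electrode appears at inconsistent positions.
#' @export
hemisphere_positions <- function(lines) {
  out <- NULL
  for (i in seq_len(nrow(lines))) {
    out <- rbind(out, data.frame(label = line_electrodes(lines, lines$line_id[i]),
                                 hemisphere = lines$hemisphere[i],
                                 position = 1:7, stringsAsFactors = FALSE))
  }
  u <- unique(out)
  if (anyDuplicated(u[c("hemisphere", "label")]))
    .stopf("line set places some electrode at inconsistent positions")
  u
}

#' The full 64-channel BioSemi-style 10-20 montage used by the simulator
#' @return Character vector of 64 labels.
#' @export
biosemi64_labels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
}
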
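#' Write / read a recording as gzipped delimited text
#'
#' Plain-text interchange format: a header row of channel labels, one row
#' per sample, tab-separated, gzip-compressed. Sampling rate and channel
#' count travel in a JSON sidecar (`<path>.json`).
#'
#' @param rec An `lfp_recording`.
#' @param path Output path (`.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  con <- gzfile(path, "w")
  on.exit(close(con))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channel_labels = rec$channel_labels,
                            n_samples = ncol(rec$data)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @param events Optional event table to embed in the returned recording
#'   (e.g. from [read_events_tsv()]).
#' @return For the reader, an `lfp_recording`.
#' @export
read_recording_tsv <- function(path, events = NULL) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.table(gzfile(path), header = TRUE, sep = "\t",
                   check.names = FALSE)
  new_recording(t(as.matrix(df)), side$fs, names(df), events)
}

#' Write / read a trial event table
#'
#' Tab-separated, one row per event, with the header contract
#' `onset_s, event, trial_index, outcome, prev_outcome, novelty,
#' expectancy_class, rt_ms`.
#'
#' @param events Event `data.frame` (see [simulate_lfp()]).
#' @param path Output `.tsv` path.
#' @return `path` invisibly; the reader returns the `data.frame`.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(is.data.frame(events))
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as EDF
#'
#' Minimal European Data Format writer: one data record per second,
#' physical units microvolts, 16-bit samples scaled to each channel's
#' physical range. The recording is zero-padded to a whole number of
#' seconds; the sampling rate must be an integer. Events are not stored in
#' EDF - keep them in the TSV sidecar ([write_events_tsv()]).
#'
#' @param rec An `lfp_recording`.
#' @param path Output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ceiling(ncol(rec$data) / fs)
  data <- rec$data
  if (ncol(data) < n_rec * fs)
    data <- cbind(data, matrix(0, ns, n_rec * fs - ncol(data)))

  pmin_ <- pmax_ <- numeric(ns)
  dig <- matrix(0L, ns, n_rec * fs)
  for (ch in seq_len(ns)) {
    # round the physical range up to the header's 2-decimal precision so
    # the stored affine map is exactly the one used for digitization
    m <- ceiling(max(abs(data[ch, ]), 1e-2) * 100) / 100
    pmin_[ch] <- -m; pmax_[ch] <- m
    scale <- (2 * m) / 65535
    dig[ch, ] <- pmin(pmax(as.integer(round((data[ch, ] + m) / scale)) - 32768L,
                           -32768L), 32767L)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X X X X", 80), .edf_pad("Startdate X X X X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad("1", 8), .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.2f", pmin_), 8)
  field(sprintf("%.2f", pmax_), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    sl <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      writeBin(dig[ch, sl], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Counterpart of [write_recording_edf()]; reads any plain EDF file with a
#' uniform per-channel rate and an integer record duration.
#'
#' @param path `.edf` path.
#' @param events Optional event table to attach.
#' @return An `lfp_recording` in physical units.
#' @export
read_recording_edf <- function(path, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header length (recomputed from ns)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  many <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- many(16); many(80); many(8)
  pmin_ <- as.numeric(many(8)); pmax_ <- as.numeric(many(8))
  dmin_ <- as.numeric(many(8)); dmax_ <- as.numeric(many(8))
  many(80)
  spr <- as.integer(many(8))
  many(32)
  if (length(unique(spr)) != 1) stop("channels with differing rates not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      sl <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      scale <- (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
      data[ch, sl] <- pmin_[ch] + (raw - dmin_[ch]) * scale
    }
  }
  new_recording(data, fs, labels, events)
}
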
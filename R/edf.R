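# Minimal European Data Format (EDF) export/import for continuous recordings.
# Plain EDF: ASCII fixed-width headers, 16-bit little-endian samples, one
# 1-second data record per block; the event schedule travels separately as
# TSV (write_events_tsv). Physical units are microvolts.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  if (nchar(s) > width) s <- substr(s, 1, width)
  s
}

edf_num <- function(x, width) edf_field(signif(x, width - 2), width)

#' Export a recording to EDF
#'
#' Writes plain EDF (16-bit) with one data record per second; the final
#' record is zero-padded. Per-channel physical scaling covers the observed
#' data range, so round-tripping is exact up to the 16-bit quantisation step.
#'
#' @param rec A `p300_recording` (or any list with `data`, `channel_names`,
#'   `sfreq`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @seealso [read_recording_edf()]
#' @export
write_recording_edf <- function(rec, path) {
  data <- rec$data
  ns <- nrow(data)
  sf <- rec$sfreq
  if (sf != round(sf))
    stop_param("EDF export requires an integer sampling rate")
  n_rec <- ceiling(ncol(data) / sf)
  pmin <- apply(data, 1, min)
  pmax <- apply(data, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("synthetic subject", 80),
    edf_field("p300prognosis synthetic recording", 80),
    edf_field("01.01.26", 8), edf_field("00.00.00", 8),
    edf_field(256 + 256 * ns, 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field(1, 8), edf_field(ns, 4),
    paste(vapply(rec$channel_names, edf_field, "", 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", 8), collapse = ""),
    paste(rep(edf_field(-32768, 8), ns), collapse = ""),
    paste(rep(edf_field(32767, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(sf, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  # header fields were written as ASCII; re-read scaling for exact inversion
  pmin_r <- as.numeric(vapply(pmin, edf_num, "", 8))
  pmax_r <- as.numeric(vapply(pmax, edf_num, "", 8))
  gain <- (pmax_r - pmin_r) / 65535
  padded <- cbind(data, matrix(0, ns, n_rec * sf - ncol(data)))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * sf + 1):(r * sf)
    for (c_i in seq_len(ns)) {
      dig <- round((padded[c_i, cols] - pmin_r[c_i]) / gain[c_i]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_recording_edf()]
#'
#' @param path EDF file.
#' @param events_path Optional events TSV to attach as the schedule.
#' @return A `p300_recording` (schedule `NULL` unless `events_path` given).
#' @export
read_recording_edf <- function(path, events_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  stopifnot(length(unique(spr)) == 1L)
  gain <- (pmax - pmin) / (dmax - dmin)
  data <- matrix(0, ns, n_rec * spr[1],
                 dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (c_i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                     endian = "little")
      data[c_i, cols] <- (dig - dmin[c_i]) * gain[c_i] + pmin[c_i]
    }
  }
  schedule <- if (!is.null(events_path)) read_events_tsv(events_path)
  structure(list(data = data, channel_names = labels,
                 sfreq = spr[1] / rec_dur, schedule = schedule),
            class = "p300_recording")
}
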
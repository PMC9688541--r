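#' Zero-phase band-pass filter a recording
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), so the filter is zero-phase and does not shift
#' the P300 peak latency. The detection path of the pipeline uses
#' 0.1--10 Hz; the ERP-figure path uses 0.1--20 Hz.
#'
#' @param rec A `p300_recording`.
#' @param low_hz,high_hz Band edges in Hz; `0 < low < high < sfreq/2`.
#' @return A filtered copy of `rec`.
#' @export
bandpass_filter <- function(rec, low_hz = 0.1, high_hz = 10) {
  if (!inherits(rec, "p300_recording"))
    stop_param("rec must be a p300_recording")
  ny <- rec$sfreq / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < ny))
    stop_param("band must satisfy 0 < low < high < sfreq/2 (Nyquist ", ny,
               " Hz)")
  bf <- signal::butter(4, c(low_hz, high_hz) / ny, type = "pass")
  out <- rec
  for (i in seq_len(nrow(rec$data)))
    out$data[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  out$filter_band <- c(low_hz, high_hz)
  out
}

# Sample-index convention: half-open [start, end) in seconds with
# index = floor(t * sfreq); 0--600 ms at 250 Hz -> 150 samples,
# -50--0 ms -> 13 samples.
window_indices <- function(window_ms, sfreq) {
  i0 <- floor(window_ms[1] / 1000 * sfreq)
  i1 <- floor(window_ms[2] / 1000 * sfreq) - 1
  seq.int(i0, i1)
}

#' Extract per-stimulus epochs from a recording
#'
#' Cuts one epoch per scheduled event, relative to the stimulus onset, using
#' a half-open sample-window convention (`index = floor(t * sfreq)`), so a
#' 0--600 ms window at 250 Hz yields 150 samples and a -50--600 ms window
#' 163. If `baseline_ms` is given, the per-channel mean of the baseline
#' interval is subtracted from each epoch.
#'
#' @param rec A `p300_recording`.
#' @param schedule Event schedule (defaults to `rec$schedule`).
#' @param window_ms Length-2 vector, epoch window in ms relative to onset.
#' @param baseline_ms Optional length-2 vector, baseline interval in ms
#'   (must lie inside `window_ms`), or `NULL` for no correction.
#' @return An object of class `p300_epochs`: list with `epochs`
#'   (n_epochs x channels x samples array), `labels` (1 = target/P300,
#'   0 = non-target), `window_ms`, `times_ms`, `sfreq`, `channel_names`.
#' @export
extract_epochs <- function(rec, schedule = rec$schedule,
                           window_ms = c(0, 600), baseline_ms = NULL) {
  if (!inherits(rec, "p300_recording"))
    stop_param("rec must be a p300_recording")
  if (is.null(schedule)) stop_param("recording has no event schedule")
  idx <- window_indices(window_ms, rec$sfreq)
  n_samp <- ncol(rec$data)
  first <- schedule$onset_sample + idx[1]
  last <- schedule$onset_sample + idx[length(idx)]
  bad <- which(first < 1 | last > n_samp)
  if (length(bad))
    stop_param("epoch window extends past recording bounds for event(s) ",
               paste(head(bad, 5), collapse = ", "))
  n_ev <- nrow(schedule)
  n_ch <- nrow(rec$data)
  ep <- array(0, dim = c(n_ev, n_ch, length(idx)))
  for (e in seq_len(n_ev))
    ep[e, , ] <- rec$data[, schedule$onset_sample[e] + idx]
  if (!is.null(baseline_ms)) {
    if (baseline_ms[1] < window_ms[1] || baseline_ms[2] > window_ms[2])
      stop_param("baseline interval must lie inside the epoch window")
    b_idx <- which(idx %in% window_indices(baseline_ms, rec$sfreq))
    if (!length(b_idx)) stop_param("baseline interval contains no samples")
    bl <- apply(ep[, , b_idx, drop = FALSE], c(1, 2), mean)
    ep <- ep - as.vector(bl)  # recycles over the 3rd dimension
  }
  structure(list(epochs = ep,
                 labels = as.integer(schedule$is_target),
                 window_ms = window_ms,
                 baseline_ms = baseline_ms,
                 times_ms = idx / rec$sfreq * 1000,
                 sfreq = rec$sfreq,
                 channel_names = rec$channel_names),
            class = "p300_epochs")
}

#' @export
print.p300_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "<p300_epochs> %d epochs x %d channels x %d samples, window %g..%g ms\n",
    d[1], d[2], d[3], x$window_ms[1], x$window_ms[2]))
  cat(sprintf("  labels: %d target, %d non-target\n",
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Build decimated, concatenated feature vectors
#'
#' For each epoch, keeps every `decim`-th sample (starting at the first
#' sample of the window) of each selected channel and concatenates the
#' decimated segments in the given channel order. With the defaults of the
#' detection path -- 600 ms epochs at 250 Hz, decimation 5, the ten feature
#' channels -- each epoch maps to a 300-dimensional vector. No additional
#' anti-alias filter is applied: the detection path is already low-passed at
#' 10 Hz, below the post-decimation Nyquist frequency of 25 Hz.
#'
#' @param epochs A `p300_epochs`.
#' @param channels Channels to use, in concatenation order.
#' @param decim Integer decimation factor (>= 1).
#' @return An object of class `p300_features`: list with `x`
#'   (n_epochs x d matrix), `labels`, `channels`, `decim`, `n_times`
#'   (decimated samples per channel) and `provenance`.
#' @export
build_feature_vectors <- function(epochs, channels = feature_channels(),
                                  decim = 5L) {
  if (!inherits(epochs, "p300_epochs"))
    stop_param("epochs must be a p300_epochs")
  if (!is_count(decim) || decim < 1) stop_param("decim must be >= 1")
  miss <- setdiff(channels, epochs$channel_names)
  if (length(miss))
    stop_param("channel(s) not present: ", paste(miss, collapse = ", "),
               "; available: ", paste(epochs$channel_names, collapse = ", "))
  ch_idx <- match(channels, epochs$channel_names)
  keep <- seq(1L, dim(epochs$epochs)[3], by = decim)
  n_ep <- dim(epochs$epochs)[1]
  blocks <- lapply(ch_idx, function(ci)
    matrix(epochs$epochs[, ci, keep], nrow = n_ep))
  x <- do.call(cbind, blocks)
  structure(list(x = x, labels = epochs$labels, channels = channels,
                 decim = as.integer(decim), n_times = length(keep),
                 provenance = list(window_ms = epochs$window_ms,
                                   sfreq = epochs$sfreq,
                                   decim = as.integer(decim),
                                   channels = channels)),
            class = "p300_features")
}

#' @export
print.p300_features <- function(x, ...) {
  cat(sprintf("<p300_features> %d epochs x %d features (%d channels x %d samples, decim %d)\n",
              nrow(x$x), ncol(x$x), length(x$channels), x$n_times, x$decim))
  invisible(x)
}

#' Save / load a feature matrix as a binary array with JSON sidecar
#'
#' The matrix is stored as little-endian doubles (`<path>.bin`) with a JSON
#' sidecar (`<path>.json`) holding dimensions, labels and provenance.
#'
#' @param features A `p300_features`.
#' @param path Base path (without extension).
#' @export
write_feature_matrix <- function(features, path) {
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.vector(features$x), con, size = 8, endian = "little")
  close(con)
  meta <- list(n = nrow(features$x), d = ncol(features$x),
               labels = features$labels, channels = features$channels,
               decim = features$decim, n_times = features$n_times,
               provenance = features$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  x <- readBin(con, "double", n = meta$n * meta$d, size = 8,
               endian = "little")
  close(con)
  structure(list(x = matrix(x, meta$n, meta$d),
                 labels = as.integer(meta$labels),
                 channels = meta$channels, decim = meta$decim,
                 n_times = meta$n_times, provenance = meta$provenance),
            class = "p300_features")
}

#' Average target and non-target ERP waveforms
#'
#' Elementwise mean over epochs within each class, per channel. Both classes
#' must be present.
#'
#' @param epochs A `p300_epochs` (typically -50--600 ms, baseline-corrected,
#'   from the 0.1--20 Hz ERP path).
#' @return Object of class `p300_erp`: `target` and `nontarget`
#'   channels x samples matrices, `n_target`, `n_nontarget`, `times_ms`,
#'   `sfreq`, `channel_names`.
#' @export
average_erp <- function(epochs) {
  if (!inherits(epochs, "p300_epochs"))
    stop_param("epochs must be a p300_epochs")
  n_t <- sum(epochs$labels == 1L)
  n_n <- sum(epochs$labels == 0L)
  if (n_t == 0L || n_n == 0L)
    stop_param("both classes must be present (have ", n_t, " target, ",
               n_n, " non-target)")
  avg <- function(sel) {
    m <- apply(epochs$epochs[sel, , , drop = FALSE], c(2, 3), mean)
    rownames(m) <- epochs$channel_names
    m
  }
  structure(list(target = avg(epochs$labels == 1L),
                 nontarget = avg(epochs$labels == 0L),
                 n_target = n_t, n_nontarget = n_n,
                 times_ms = epochs$times_ms, sfreq = epochs$sfreq,
                 channel_names = epochs$channel_names),
            class = "p300_erp")
}

#' @export
print.p300_erp <- function(x, ...) {
  cat(sprintf("<p300_erp> %d channels, %g..%g ms, %d target / %d non-target epochs averaged\n",
              nrow(x$target), min(x$times_ms), max(x$times_ms),
              x$n_target, x$n_nontarget))
  invisible(x)
}

#' Plot grand-average ERP waveforms at one channel
#'
#' @param x A `p300_erp`.
#' @param channel Channel to plot (default Pz).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.p300_erp <- function(x, channel = "Pz", ...) {
  ci <- match(channel, x$channel_names)
  if (is.na(ci)) stop_param("unknown channel ", channel)
  graphics::matplot(x$times_ms, cbind(x$target[ci, ], x$nontarget[ci, ]),
                    type = "l", lty = 1, col = c("firebrick", "grey40"),
                    xlab = "time after stimulus (ms)",
                    ylab = expression(paste("amplitude (", mu, "V)")),
                    main = paste0("Grand-average ERP at ", channel), ...)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", c("target", "non-target"), lty = 1,
                   col = c("firebrick", "grey40"), bty = "n")
  invisible(x)
}

#' Export ERP waveforms to CSV
#'
#' One row per sample; columns `time_ms` then `<channel>_target` and
#' `<channel>_nontarget` per channel.
#'
#' @param erp A `p300_erp`.
#' @param path Output CSV.
#' @export
write_erp_csv <- function(erp, path) {
  df <- data.frame(time_ms = erp$times_ms)
  for (ch in erp$channel_names) {
    df[[paste0(ch, "_target")]] <- erp$target[ch, ]
    df[[paste0(ch, "_nontarget")]] <- erp$nontarget[ch, ]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
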
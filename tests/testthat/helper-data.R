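# Shared fixtures, generated once per test run.

# A mid-sized synthetic patient through the detection path (filter, epoch,
# decimate); cached because several files use it.
shared_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(100, 100, seed = 42)
      rec <- bandpass_filter(generate_recording(cfg), 0.1, 10)
      cache <<- build_feature_vectors(extract_epochs(rec))
    }
    cache
  }
})

# Two well-separated Gaussian blobs shaped like (n_channels x n_times)
# feature images; linearly separable by construction.
make_blobs <- function(n_per_class = 200, n_channels = 4, n_times = 10,
                       sep = 4, seed = 1) {
  d <- n_channels * n_times
  withr::with_seed(seed, {
    dir <- rnorm(d)
    dir <- dir / sqrt(sum(dir^2))
    x <- rbind(matrix(rnorm(n_per_class * d), n_per_class),
               matrix(rnorm(n_per_class * d), n_per_class) +
                 matrix(sep * dir, n_per_class, d, byrow = TRUE))
    list(x = x, y = rep(c(0L, 1L), each = n_per_class),
         n_channels = n_channels, n_times = n_times)
  })
}

# A tiny recording with a known deterministic data matrix, for epoch /
# feature arithmetic tests.
toy_recording <- function(data, sfreq = 250, onsets = NULL,
                          is_target = NULL) {
  ch <- montage_30()[seq_len(nrow(data))]
  rownames(data) <- ch
  n_ev <- length(onsets)
  structure(list(
    data = data, channel_names = ch, sfreq = sfreq,
    schedule = if (!is.null(onsets))
      data.frame(onset_sample = onsets,
                 onset_ms = (onsets - 1) / sfreq * 1000,
                 side = rep(c("left", "right"), length.out = n_ev),
                 is_target = is_target)),
    class = "p300_recording")
}
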
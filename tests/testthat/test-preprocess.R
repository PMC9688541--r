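make_sine_rec <- function(freq, sfreq = 250, dur_s = 20) {
  t <- seq(0, dur_s - 1 / sfreq, by = 1 / sfreq)
  toy_recording(matrix(sin(2 * pi * freq * t), nrow = 1), sfreq = sfreq)
}

test_that("band-pass filter rejects DC and stop-band, passes the pass-band", {
  sf <- 250
  # the 0.1 Hz high-pass settles on a ~10 s timescale, so judge DC
  # rejection away from the forward-backward edge transients
  dc <- toy_recording(matrix(1, 1, 50000), sfreq = sf)
  out <- bandpass_filter(dc, 0.1, 10)
  expect_lt(max(abs(out$data[1, 10000:40000])), 1e-4)
  expect_lt(mean(abs(out$data)), 0.05)

  rms <- function(x) sqrt(mean(x^2))
  line <- make_sine_rec(50)
  keep <- 1000:4000  # interior, away from filtfilt edge transients
  expect_lt(rms(bandpass_filter(line, 0.1, 10)$data[1, keep]) /
              rms(line$data[1, keep]), 0.01)
  pass <- make_sine_rec(5)
  expect_lt(abs(rms(bandpass_filter(pass, 0.1, 10)$data[1, keep]) /
                  rms(pass$data[1, keep]) - 1), 0.05)
})

test_that("filter is linear and validates its band", {
  rec <- generate_recording(synthetic_config(5, 5, seed = 2))
  a <- rec; b <- rec
  b$data <- rec$data[30:1, ]  # a different signal, same shape
  comb <- rec
  comb$data <- 2 * a$data + 3 * b$data
  # tight check on a mild band, where the recursion is well conditioned
  lhs <- bandpass_filter(comb, 1, 30)$data
  rhs <- 2 * bandpass_filter(a, 1, 30)$data +
    3 * bandpass_filter(b, 1, 30)$data
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # the 0.1 Hz pole sits near the unit circle and amplifies float error;
  # linearity then holds to a correspondingly looser tolerance
  lhs2 <- bandpass_filter(comb, 0.1, 10)$data
  rhs2 <- 2 * bandpass_filter(a, 0.1, 10)$data +
    3 * bandpass_filter(b, 0.1, 10)$data
  expect_lt(max(abs(lhs2 - rhs2)) / max(abs(lhs2)), 5e-3)
  expect_error(bandpass_filter(rec, 0, 10), "band")
  expect_error(bandpass_filter(rec, 1, 130), "band")
})

test_that("epoch windows follow the floor-index half-open convention", {
  rec <- generate_recording(synthetic_config(10, 10, seed = 6))
  expect_equal(dim(extract_epochs(rec, window_ms = c(0, 600))$epochs)[3], 150)
  ep <- extract_epochs(rec, window_ms = c(-50, 600),
                       baseline_ms = c(-50, 0))
  expect_equal(dim(ep$epochs)[3], 163)
  expect_equal(sum(ep$times_ms < 0), 13)
})

test_that("baseline correction zeroes a constant epoch and the stored mean", {
  data <- matrix(1, nrow = 2, ncol = 1000)
  rec <- toy_recording(data, onsets = c(101L, 401L),
                       is_target = c(TRUE, FALSE))
  ep <- extract_epochs(rec, window_ms = c(-50, 600), baseline_ms = c(-50, 0))
  expect_equal(max(abs(ep$epochs)), 0)
  # baseline interval of averaged waveforms is 0 after correction
  cfg <- synthetic_config(30, 30, seed = 12)
  ep2 <- extract_epochs(generate_recording(cfg), window_ms = c(-50, 600),
                        baseline_ms = c(-50, 0))
  erp <- average_erp(ep2)
  bl <- erp$times_ms < 0
  expect_lt(max(abs(rowMeans(erp$target[, bl]))), 1e-9)
  expect_lt(max(abs(rowMeans(erp$nontarget[, bl]))), 1e-9)
})

test_that("epochs extending past the recording report the offending event", {
  data <- matrix(0, nrow = 1, ncol = 300)
  rec <- toy_recording(data, onsets = c(50L, 250L), is_target = c(TRUE, FALSE))
  expect_error(extract_epochs(rec, window_ms = c(0, 600)), "event\\(s\\) 2")
})

test_that("feature vectors decimate and concatenate in channel order", {
  # Pz carries a ramp 0,1,2,...; its decimated block must be 0,5,10,...
  data <- matrix(0, nrow = 30, ncol = 400)
  pz <- match("Pz", montage_30())
  data[pz, 101:250] <- 0:149
  rec <- toy_recording(data, onsets = c(101L, 102L), is_target = c(TRUE, FALSE))
  rec$schedule <- rec$schedule[1, ]
  ep <- extract_epochs(rec, window_ms = c(0, 600))
  fv <- build_feature_vectors(ep, channels = feature_channels(), decim = 5)
  expect_equal(dim(fv$x), c(1, 300))
  block <- which(feature_channels() == "Pz")
  expect_equal(fv$x[1, ((block - 1) * 30 + 1):(block * 30)],
               seq(0, 145, by = 5))
  expect_true(all(fv$x[1, -(((block - 1) * 30 + 1):(block * 30))] == 0))
})

test_that("feature dimension formula holds across configurations", {
  rec <- generate_recording(synthetic_config(6, 6, seed = 8))
  for (win in list(c(0, 600), c(0, 400))) {
    ep <- extract_epochs(rec, window_ms = win)
    n_s <- dim(ep$epochs)[3]
    for (decim in c(1L, 3L, 5L)) {
      for (chs in list("Pz", c("Fz", "Cz", "Pz"), feature_channels())) {
        fv <- build_feature_vectors(ep, channels = chs, decim = decim)
        expect_equal(ncol(fv$x), length(chs) * ceiling(n_s / decim))
      }
    }
  }
  # decim 1, single channel: the feature vector is the raw epoch
  ep <- extract_epochs(rec, window_ms = c(0, 600))
  fv <- build_feature_vectors(ep, channels = "Oz", decim = 1)
  expect_equal(fv$x[3, ], ep$epochs[3, match("Oz", ep$channel_names), ])
  expect_error(build_feature_vectors(ep, channels = "Nope"), "available")
})

test_that("feature matrices round-trip through the binary container", {
  fv <- build_feature_vectors(
    extract_epochs(generate_recording(synthetic_config(8, 8, seed = 4))))
  base <- withr::local_tempfile()
  write_feature_matrix(fv, base)
  fv2 <- read_feature_matrix(base)
  expect_equal(fv2$x, fv$x)
  expect_equal(fv2$labels, fv$labels)
  expect_equal(fv2$provenance$decim, fv$provenance$decim)
})

test_that("ERP averaging is the within-class mean and needs both classes", {
  data <- matrix(rnorm(30 * 1200), nrow = 30)
  rec <- toy_recording(data, onsets = c(101L, 401L, 701L),
                       is_target = c(TRUE, TRUE, FALSE))
  ep <- extract_epochs(rec, window_ms = c(0, 600))
  erp <- average_erp(ep)
  expect_equal(erp$target, (ep$epochs[1, , ] + ep$epochs[2, , ]) / 2,
               ignore_attr = TRUE)
  expect_equal(erp$nontarget, ep$epochs[3, , ], ignore_attr = TRUE)
  # two identical target epochs average to the epoch itself
  rec2 <- toy_recording(data, onsets = c(101L, 101L, 401L),
                        is_target = c(TRUE, TRUE, FALSE))
  erp2 <- average_erp(extract_epochs(rec2, window_ms = c(0, 600)))
  expect_equal(erp2$target, ep$epochs[1, , ], ignore_attr = TRUE)
  ep$labels <- rep(1L, 3)
  expect_error(average_erp(ep), "both classes")
})

test_that("the detection pipeline is byte-deterministic", {
  run <- function() {
    rec <- bandpass_filter(generate_recording(synthetic_config(15, 15, seed = 21)),
                           0.1, 10)
    build_feature_vectors(extract_epochs(rec))
  }
  expect_identical(run()$x, run()$x)
})
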
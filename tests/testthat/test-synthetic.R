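test_that("config validation rejects bad parameters", {
  expect_error(synthetic_config(-1, 10), "non-negative")
  expect_error(synthetic_config(10, 10, sfreq = 0), "positive")
  expect_error(synthetic_config(10, 10, p300_amplitude = -2), ">= 0")
  expect_error(synthetic_config(10, 10, soa = 500), "at least 600")
})

test_that("schedule has the required event structure", {
  rec <- generate_recording(synthetic_config(550, 550, seed = 5))
  sch <- rec$schedule
  expect_equal(nrow(sch), 1100)
  expect_equal(sum(sch$is_target), 550)
  # strictly increasing onsets with gaps covering the 600 ms epoch window
  expect_true(all(diff(sch$onset_sample) > 0))
  expect_true(all(diff(sch$onset_sample) >= 0.6 * rec$sfreq))
  # flash positions alternate between consecutive events
  expect_true(all(sch$side[-1] != sch$side[-nrow(sch)]))
  # recording covers the last epoch
  expect_gte(ncol(rec$data), max(sch$onset_sample) + 0.6 * rec$sfreq)
  expect_equal(nrow(rec$data), 30)
  expect_true(all(feature_channels() %in% rec$channel_names))
})

test_that("identical config and seed give bit-identical recordings", {
  a <- generate_recording(synthetic_config(30, 30, seed = 9))
  b <- generate_recording(synthetic_config(30, 30, seed = 9))
  expect_identical(a$data, b$data)
  expect_identical(a$schedule, b$schedule)
  c <- generate_recording(synthetic_config(30, 30, seed = 10))
  expect_false(identical(a$data, c$data))
})

test_that("target-minus-nontarget ERP recovers the configured amplitude", {
  # averaging 2000 epochs per class cancels the shared background noise
  cfg <- synthetic_config(2000, 2000, p300_amplitude = 5,
                          latency_jitter_sd = 0, seed = 31)
  rec <- generate_recording(cfg)
  erp <- average_erp(extract_epochs(rec))
  dif <- erp$target["Pz", ] - erp$nontarget["Pz", ]
  pk <- which.max(dif)
  expect_gte(erp$times_ms[pk], 250)
  expect_lte(erp$times_ms[pk], 350)
  expect_lt(abs(dif[pk] - 5) / 5, 0.10)
})

test_that("zero amplitude leaves the classes exchangeable", {
  # per-epoch Pz means: two-sample p-values behave like a null across seeds
  ps <- vapply(1:10, function(s) {
    cfg <- synthetic_config(40, 40, p300_amplitude = 0, seed = 100 + s)
    ep <- extract_epochs(generate_recording(cfg))
    pz <- apply(ep$epochs[, match("Pz", ep$channel_names), ], 1, mean)
    t.test(pz[ep$labels == 1], pz[ep$labels == 0])$p.value
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 2)
  expect_gt(max(ps), 0.3)
})

test_that("background noise obeys the configured 1/f spectral slope", {
  for (ex in c(0.7, 1, 1.3)) {
    cfg <- synthetic_config(60, 60, p300_amplitude = 0,
                            line_noise_amplitude = 0,
                            noise = list(exponent = ex, pink_rms = 9,
                                         white_rms = 0),
                            seed = 77)
    rec <- generate_recording(cfg)
    x <- rec$data[1, ]
    n <- length(x)
    pw <- Mod(fft(x))^2 / n
    f <- (seq_len(n) - 1) * rec$sfreq / n
    band <- f >= 1 & f <= 30
    slope <- unname(coef(lm(log(pw[band]) ~ log(f[band])))[2])
    expect_lt(abs(-slope - ex), 0.2)
  }
})

test_that("cohort generation validates inputs and stays deterministic", {
  expect_error(generate_cohort(list()), "non-empty")
  cfgs <- list(synthetic_config(10, 10, seed = 1),
               synthetic_config(10, 10, seed = 2))
  expect_error(generate_cohort(cfgs, ids = c("P1", "P1")), "duplicate")
  coh <- generate_cohort(cfgs, ids = c("A", "B"))
  expect_length(coh, 2)
  man <- attr(coh, "manifest")
  expect_equal(man$patient_id, c("A", "B"))
  expect_equal(man$seed, c(1L, 2L))
  # two configs sharing seed and parameters give bit-identical data
  coh2 <- generate_cohort(list(synthetic_config(10, 10, seed = 1),
                               synthetic_config(10, 10, seed = 1)))
  expect_identical(coh2[[1]]$data, coh2[[2]]$data)
})

test_that("the published epoch-count table maps onto a full-size cohort", {
  counts <- load_epoch_counts()
  cfgs <- configs_from_epoch_counts(counts)
  expect_length(cfgs, 18)
  tot <- vapply(cfgs, function(cg) cg$n_target + cg$n_nontarget, numeric(1))
  expect_equal(sum(tot), 41240)  # sum of the per-patient totals
  expect_equal(unname(tot[1]), 1100)
  expect_equal(length(unique(vapply(cfgs, `[[`, integer(1), "seed"))), 18)
})

test_that("schedules and configs round-trip through their text formats", {
  rec <- generate_recording(synthetic_config(12, 12, seed = 3))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(rec$schedule, tsv)
  ev <- read_events_tsv(tsv)
  expect_equal(ev$onset_sample, rec$schedule$onset_sample)
  expect_equal(ev$is_target, rec$schedule$is_target)

  yml <- withr::local_tempfile(fileext = ".yaml")
  cfg <- synthetic_config(12, 12, p300_amplitude = 3.5, seed = 3)
  write_synthetic_config(cfg, yml)
  cfg2 <- read_synthetic_config(yml)
  expect_equal(cfg2$p300_amplitude, 3.5)
  expect_identical(generate_recording(cfg2)$data,
                   generate_recording(cfg)$data)
})
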
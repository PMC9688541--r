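#' Standard 30-channel montage
#'
#' Channel names of the 30-electrode cap used throughout the package, in
#' recording order. It contains the ten posterior/midline channels used for
#' feature extraction (Fz, Cz, P7, P3, Pz, P4, P8, O1, Oz, O2).
#'
#' @return Character vector of 30 channel names.
#' @export
montage_30 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2")
}

#' The ten feature channels of the detection pipeline
#'
#' @return Character vector: Fz, Cz, P7, P3, Pz, P4, P8, O1, Oz, O2.
#' @export
feature_channels <- function() {
  c("Fz", "Cz", "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")
}

#' Default centro-parietal P300 topography
#'
#' Per-channel weights in \[0, 1\] applied to the P300 component. The maximum
#' sits at Pz/Cz and decays toward frontal and occipital sites, the classic
#' scalp distribution of the P3b.
#'
#' @return Named numeric vector over [montage_30()].
#' @export
default_topography <- function() {
  w <- stats::setNames(rep(0.3, 30L), montage_30())
  w[c("Pz", "Cz")] <- 1.0
  w["CPz"] <- 0.9
  w[c("CP3", "CP4", "P3", "P4")] <- 0.8
  w[c("C3", "C4", "FCz")] <- 0.6
  w[c("P7", "P8", "O1", "Oz", "O2", "TP7", "TP8")] <- 0.5
  w[c("Fz", "FC3", "FC4")] <- 0.4
  w
}

#' Configuration of a synthetic oddball recording
#'
#' Describes one simulated audiovisual-oddball EEG session: how many target
#' (P300-bearing) and non-target stimuli are presented, the morphology of the
#' P300 component added to target epochs, and the background-noise model.
#'
#' The P300 component is a positive Gaussian bump (default 200 ms full width
#' at half maximum) centred at `p300_latency` (plus per-event Gaussian jitter)
#' and scaled per channel by `topography`. Background noise is an independent
#' 1/f ("pink") process per channel plus white noise, with a small common
#' 50 Hz line component so that the filtering stage has mains interference to
#' remove. Amplitudes are in microvolts.
#'
#' @param n_target,n_nontarget Number of target / non-target stimuli.
#' @param p300_amplitude Peak amplitude of the P300 bump at a unit-weight
#'   channel, in microvolts.
#' @param p300_latency Latency of the bump peak after stimulus onset, ms.
#' @param latency_jitter_sd SD of the per-event Gaussian latency jitter, ms.
#' @param p300_fwhm Full width at half maximum of the bump, ms.
#' @param noise List with elements `exponent` (1/f power-law exponent),
#'   `pink_rms` (RMS of the pink process, microvolts) and `white_rms`.
#' @param topography Named per-channel weight vector in \[0, 1\];
#'   defaults to [default_topography()].
#' @param line_noise_amplitude Amplitude of the 50 Hz line component,
#'   microvolts.
#' @param sfreq Sampling frequency, Hz.
#' @param soa Stimulus-onset asynchrony, ms; must be at least 600 so that
#'   consecutive 0--600 ms epochs do not overlap.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   recordings.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_target, n_nontarget,
                             p300_amplitude = 5, p300_latency = 300,
                             latency_jitter_sd = 20, p300_fwhm = 200,
                             noise = list(exponent = 1, pink_rms = 9,
                                          white_rms = 2),
                             topography = default_topography(),
                             line_noise_amplitude = 1,
                             sfreq = 250, soa = 800, seed = 1L) {
  if (!is_count(n_target) || !is_count(n_nontarget))
    stop_param("n_target and n_nontarget must be non-negative integers")
  if (!is.numeric(sfreq) || sfreq <= 0)
    stop_param("sfreq must be positive")
  if (!is.numeric(p300_amplitude) || p300_amplitude < 0)
    stop_param("p300_amplitude must be >= 0")
  if (!is.numeric(soa) || soa < 600)
    stop_param("soa must be at least 600 ms (the epoch window length)")
  stopifnot(is.list(noise),
            all(c("exponent", "pink_rms", "white_rms") %in% names(noise)))
  if (is.null(names(topography)) || any(topography < 0) || any(topography > 1))
    stop_param("topography must be a named vector of weights in [0, 1]")
  cfg <- list(n_target = as.integer(n_target),
              n_nontarget = as.integer(n_nontarget),
              p300_amplitude = p300_amplitude, p300_latency = p300_latency,
              latency_jitter_sd = latency_jitter_sd, p300_fwhm = p300_fwhm,
              noise = noise, topography = topography,
              line_noise_amplitude = line_noise_amplitude,
              sfreq = sfreq, soa = soa, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

# Unit-RMS 1/f^exponent noise via spectral shaping of white Gaussian noise.
pink_noise <- function(n, exponent) {
  spec <- complex(length.out = n)
  half <- floor((n - 1) / 2)
  if (half > 0) {
    z <- complex(real = rnorm(half), imaginary = rnorm(half))
    spec[2:(half + 1)] <- z * seq_len(half)^(-exponent / 2)
    spec[n:(n - half + 1)] <- Conj(spec[2:(half + 1)])
  }
  if (n %% 2 == 0)
    spec[n / 2 + 1] <- rnorm(1) * (n / 2)^(-exponent / 2)
  x <- Re(stats::fft(spec, inverse = TRUE))
  x / sqrt(mean(x^2))
}

#' Generate one synthetic oddball EEG recording
#'
#' Simulates a continuous multichannel recording together with its stimulus
#' event schedule. Stimuli alternate between the left and right flash
#' positions at a fixed stimulus-onset asynchrony; target/non-target order is
#' randomised. Target events receive an additive positive P300 component on
#' top of the same background-noise process that both classes share.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `p300_recording`: a list with `data`
#'   (channels x samples matrix, microvolts), `channel_names`, `sfreq` and
#'   `schedule` (data frame with `onset_sample` (1-based), `onset_ms`,
#'   `side`, `is_target`).
#' @examples
#' rec <- generate_recording(synthetic_config(20, 20, seed = 7))
#' dim(rec$data)
#' @export
generate_recording <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop_param("config must be a synthetic_config")
  ch <- montage_30()
  topo <- config$topography[ch]
  if (anyNA(topo))
    stop_param("topography must cover all montage channels")
  sf <- config$sfreq
  n_ev <- config$n_target + config$n_nontarget
  if (n_ev == 0L) stop_param("at least one event is required")
  soa_samp <- round(config$soa / 1000 * sf)

  with_seed(config$seed, {
    onset <- as.integer(round(sf)) + soa_samp * (seq_len(n_ev) - 1L) + 1L
    n_samp <- as.integer(onset[n_ev] + ceiling(0.6 * sf) + round(sf))
    side <- rep(c("left", "right"), length.out = n_ev)
    is_target <- sample(rep(c(TRUE, FALSE),
                            c(config$n_target, config$n_nontarget)))
    tvec <- (seq_len(n_samp) - 1L) / sf
    data <- matrix(0, nrow = 30L, ncol = n_samp, dimnames = list(ch, NULL))
    for (c_i in seq_len(30L)) {
      x <- config$noise$pink_rms * pink_noise(n_samp, config$noise$exponent) +
        config$noise$white_rms * rnorm(n_samp)
      if (config$line_noise_amplitude > 0)
        x <- x + config$line_noise_amplitude *
          sin(2 * pi * 50 * tvec + runif(1, 0, 2 * pi))
      data[c_i, ] <- x
    }
    # additive P300 on target epochs: Gaussian bump, per-event latency jitter
    if (config$n_target > 0L && config$p300_amplitude > 0) {
      sigma_s <- config$p300_fwhm / 1000 / (2 * sqrt(2 * log(2)))
      support <- 0:ceiling(0.75 * sf)
      lat <- config$p300_latency / 1000 +
        rnorm(sum(is_target), 0, config$latency_jitter_sd / 1000)
      k <- 0L
      for (e in which(is_target)) {
        k <- k + 1L
        bump <- config$p300_amplitude *
          exp(-((support / sf - lat[k])^2) / (2 * sigma_s^2))
        idx <- onset[e] + support
        data[, idx] <- data[, idx] + outer(unname(topo), bump)
      }
    }
    schedule <- data.frame(onset_sample = onset,
                           onset_ms = (onset - 1L) / sf * 1000,
                           side = side, is_target = is_target,
                           stringsAsFactors = FALSE)
    structure(list(data = data, channel_names = ch, sfreq = sf,
                   schedule = schedule, config = config),
              class = "p300_recording")
  })
}

#' @export
print.p300_recording <- function(x, ...) {
  cat(sprintf("<p300_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  cat(sprintf("  events: %d (%d target, %d non-target)\n",
              nrow(x$schedule), sum(x$schedule$is_target),
              sum(!x$schedule$is_target)))
  invisible(x)
}

#' Generate a cohort of synthetic patients
#'
#' One recording per configuration, with a manifest linking each recording to
#' a patient identifier. Configurations may differ in epoch counts, P300
#' amplitude and noise, emulating a heterogeneous patient cohort.
#'
#' @param configs List of [synthetic_config()] objects.
#' @param ids Patient identifiers (default `P1`, `P2`, ...); must be unique.
#' @return Named list of `p300_recording` objects of class `p300_cohort`,
#'   with a `manifest` attribute (data frame: patient_id, seed, n_target,
#'   n_nontarget, sfreq).
#' @export
generate_cohort <- function(configs, ids = paste0("P", seq_along(configs))) {
  if (!is.list(configs) || length(configs) == 0L)
    stop_param("configs must be a non-empty list of synthetic_config objects")
  if (!all(vapply(configs, inherits, logical(1), "synthetic_config")))
    stop_param("every element of configs must be a synthetic_config")
  if (anyDuplicated(ids))
    stop_param("duplicate patient identifiers: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ids) != length(configs))
    stop_param("ids must match configs in length")
  recs <- lapply(configs, generate_recording)
  names(recs) <- ids
  manifest <- data.frame(
    patient_id = ids,
    seed = vapply(configs, `[[`, integer(1), "seed"),
    n_target = vapply(configs, `[[`, integer(1), "n_target"),
    n_nontarget = vapply(configs, `[[`, integer(1), "n_nontarget"),
    sfreq = vapply(configs, `[[`, numeric(1), "sfreq"),
    stringsAsFactors = FALSE)
  structure(recs, class = "p300_cohort", manifest = manifest)
}

#' Build per-patient configs from an epoch-count table
#'
#' Maps a table of per-patient target/non-target epoch counts (columns
#' `patient_id`, `n_p300`, `n_non_p300`) to a list of synthetic
#' configurations, assigning each patient a distinct seed derived from
#' `base_seed`.
#'
#' @param counts Data frame as returned by [load_epoch_counts()].
#' @param base_seed Integer; patient `i` receives seed `base_seed + i`.
#' @param ... Further arguments passed to [synthetic_config()].
#' @return Named list of `synthetic_config` objects.
#' @export
configs_from_epoch_counts <- function(counts, base_seed = 1L, ...) {
  stopifnot(all(c("patient_id", "n_p300", "n_non_p300") %in% names(counts)))
  cfgs <- lapply(seq_len(nrow(counts)), function(i)
    synthetic_config(counts$n_p300[i], counts$n_non_p300[i],
                     seed = base_seed + i, ...))
  names(cfgs) <- counts$patient_id
  cfgs
}

#' Write / read a stimulus event schedule as TSV
#'
#' Columns: `onset_sample`, `onset_ms`, `side`, `is_target`.
#'
#' @param schedule Schedule data frame from a `p300_recording`.
#' @param path Output file.
#' @export
write_events_tsv <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset_sample", "onset_ms", "side", "is_target")
                %in% names(ev)))
  ev$is_target <- as.logical(ev$is_target)
  ev
}

#' Serialise a synthetic configuration to a text file
#'
#' YAML key-value representation; [read_synthetic_config()] restores an
#' equivalent `synthetic_config`.
#'
#' @param config A [synthetic_config()].
#' @param path File path.
#' @export
write_synthetic_config <- function(config, path) {
  x <- unclass(config)
  x$topography <- as.list(x$topography)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(synthetic_config, c(
    x[setdiff(names(x), "topography")],
    list(topography = unlist(x$topography))))
}
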
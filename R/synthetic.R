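#' Synthetic phonocardiogram configuration
#'
#' Describes the generative model for labelled synthetic heart-sound
#' recordings: 2000 Hz mono signals of periodic cardiac cycles, each
#' cycle carrying an S1 burst (Gaussian-enveloped tone drawn from the
#' `s1_freq` band) and an S2 burst (`s2_freq` band) separated by a
#' systolic interval; "unhealthy" records additionally carry
#' band-limited murmur noise (`murmur_band`) across systole; white
#' background noise is added to every record. The default class split
#' (124 healthy / 36 unhealthy, about 77%/23%) mirrors the imbalance of
#' the public heart-sound archive the pipeline targets.
#'
#' @param n_healthy,n_unhealthy Number of records per class.
#' @param rate Sampling rate (Hz, default 2000).
#' @param duration Record length in seconds (default 10).
#' @param heart_rate Mean heart rate (beats/min, default 70).
#' @param heart_rate_jitter SD of per-record heart-rate draw (bpm).
#' @param s1_freq,s2_freq Frequency bands (Hz) the S1/S2 tone
#'   frequencies are drawn from.
#' @param systole_frac Fraction of the cycle from S1 onset to S2 onset.
#' @param murmur_band Murmur band (Hz), default 150-400.
#' @param murmur_amplitude Murmur RMS relative to the S1 burst peak
#'   amplitude (unhealthy class only).
#' @param noise_sd SD of the additive white background noise.
#' @param seed RNG seed; the full dataset is a deterministic function
#'   of the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_healthy = 124L, n_unhealthy = 36L,
                         rate = 2000L, duration = 10,
                         heart_rate = 70, heart_rate_jitter = 5,
                         s1_freq = c(30, 80), s2_freq = c(50, 120),
                         systole_frac = 0.35,
                         murmur_band = c(150, 400),
                         murmur_amplitude = 0.3, noise_sd = 0.05,
                         seed = 1L) {
  stopifnot(n_healthy + n_unhealthy >= 2L, rate > 0, duration > 0,
            heart_rate > 0, murmur_amplitude >= 0, noise_sd >= 0,
            systole_frac > 0, systole_frac < 1)
  for (band in list(s1_freq, s2_freq, murmur_band)) {
    if (max(band) >= rate / 2) {
      stop("frequency band [", paste(band, collapse = ", "),
           "] reaches the Nyquist rate ", rate / 2, " Hz")
    }
  }
  structure(list(n_healthy = as.integer(n_healthy),
                 n_unhealthy = as.integer(n_unhealthy),
                 rate = as.integer(rate), duration = duration,
                 heart_rate = heart_rate,
                 heart_rate_jitter = heart_rate_jitter,
                 s1_freq = s1_freq, s2_freq = s2_freq,
                 systole_frac = systole_frac,
                 murmur_band = murmur_band,
                 murmur_amplitude = murmur_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# Gaussian-enveloped tone burst centred at t0 (s), sd width (s).
.burst <- function(t, t0, freq, width, amp) {
  amp * exp(-(t - t0)^2 / (2 * width^2)) * sin(2 * pi * freq * (t - t0))
}

.one_pcg <- function(cfg, unhealthy) {
  fs <- cfg$rate
  t <- seq(0, cfg$duration - 1 / fs, by = 1 / fs)
  n <- length(t)
  bpm <- max(20, cfg$heart_rate + stats::rnorm(1, sd = cfg$heart_rate_jitter))
  cycle <- 60 / bpm
  systole <- cfg$systole_frac * cycle
  if (systole >= cycle) stop("systole longer than the cardiac cycle")
  f1 <- stats::runif(1, cfg$s1_freq[1], cfg$s1_freq[2])
  f2 <- stats::runif(1, cfg$s2_freq[1], cfg$s2_freq[2])
  x <- numeric(n)
  onsets <- seq(0.1, cfg$duration, by = cycle)
  for (t0 in onsets) {
    t0j <- t0 + stats::rnorm(1, sd = 0.005)          # beat-to-beat jitter
    x <- x + .burst(t, t0j, f1, 0.02, 1) +
      .burst(t, t0j + systole, f2, 0.015, 0.8)
  }
  if (unhealthy && cfg$murmur_amplitude > 0) {
    bf <- signal::butter(4, cfg$murmur_band / (fs / 2), type = "pass")
    mur <- signal::filtfilt(bf, stats::rnorm(n))
    mur <- mur / max(stats::sd(mur), 1e-12) * cfg$murmur_amplitude
    gate <- numeric(n)
    for (t0 in onsets) {                             # systolic window S1 -> S2
      gate <- gate + exp(-((t - (t0 + systole / 2))^2) / (2 * (systole / 4)^2))
    }
    x <- x + mur * pmin(gate, 1)
  }
  x <- x + stats::rnorm(n, sd = cfg$noise_sd)
  0.9 * x / max(abs(x))                              # headroom for 16-bit PCM
}

#' Generate a labelled synthetic PCG dataset
#'
#' Deterministic given the config (including its seed): calling twice
#' produces identical samples, and [write_pcg_dataset()] therefore
#' byte-identical WAV files.
#'
#' @param cfg A [synth_config()].
#' @return List with `records` (list of [pcg_record()]s, healthy first)
#'   and `labels` (factor).
#' @export
generate_pcg_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  labels <- factor(rep(c("healthy", "unhealthy"),
                       c(cfg$n_healthy, cfg$n_unhealthy)),
                   levels = c("healthy", "unhealthy"))
  ids <- sprintf("synth_%s_%03d", substr(labels, 1, 1), seq_along(labels))
  records <- lapply(seq_along(labels), function(i) {
    pcg_record(ids[i], .one_pcg(cfg, labels[i] == "unhealthy"),
               cfg$rate, as.character(labels[i]))
  })
  list(records = records, labels = labels)
}

#' Write a synthetic dataset as WAV files plus a manifest CSV
#'
#' The manifest dialect (`filename,label`) matches [load_manifest()],
#' so a written dataset round-trips through the ingestion path.
#'
#' @param dataset Output of [generate_pcg_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_pcg_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- paste0(vapply(dataset$records, `[[`, "", "id"), ".wav")
  for (i in seq_along(dataset$records)) {
    write_record(dataset$records[[i]], file.path(dir, fn[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(filename = fn,
                              label = as.character(dataset$labels)),
                   manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Mean spectral energy of records in a frequency band
#'
#' Direct periodogram band energy, used to verify that unhealthy
#' records carry excess energy in the murmur band.
#'
#' @param record A [pcg_record()].
#' @param band Frequency band (Hz), length 2.
#' @return Mean squared DFT magnitude over the band, per sample.
#' @export
band_energy <- function(record, band = c(150, 400)) {
  x <- record$samples
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) * record$rate / n
  keep <- freq >= band[1] & freq <= band[2]
  mean(sp[keep])
}
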
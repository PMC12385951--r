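# Seeded synthetic single-channel EEG-like records with controllable class
# separability, so the full pipeline (I/O, segmentation, augmentation,
# training, cross-validation) runs without any external download.
#
# Each class mixes (a) a shared AR(2) baseline with a 1/f-like spectrum,
# (b) a class-specific band-limited sinusoid (distinct center frequency per
# class within 1-40 Hz, amplitude increasing with the class index so
# per-class band power is ordered by construction), and (c) for the last,
# "ictal-like" class, high-amplitude spike-wave bursts at random onsets.
# Easy mode separates class band-power means by several within-class
# standard deviations; hard mode makes the amplitude jitter comparable to
# the class gaps.

#' Synthetic dataset settings
#'
#' @param n_classes number of classes (>= 2); class labels are the first
#'   `n_classes` letters so all downstream task machinery works unchanged.
#' @param records_per_class records generated per class.
#' @param length samples per record (>= 512; default mirrors the
#'   4097-sample Bonn records).
#' @param fs nominal sampling rate in Hz.
#' @param difficulty `"easy"` (cleanly separable band powers) or `"hard"`
#'   (overlapping).
#' @param seed master RNG seed.
#' @param ar AR(2) coefficients of the shared baseline.
#' @param noise_sd innovation standard deviation of the baseline
#'   (microvolt scale).
#' @param class_freqs center frequencies (Hz) per class; recycled/truncated
#'   to `n_classes`.
#' @param base_amp sinusoid amplitude scale; per-class amplitude is
#'   `base_amp * (1 + 0.3 * class_index)`.
#' @param amp_jitter_sd per-record amplitude jitter.
#' @param burst_amp_factor spike-burst amplitude as a multiple of the
#'   baseline standard deviation (ictal-like class only).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 5L, records_per_class = 100L,
                         length = 4097L, fs = 173.61,
                         difficulty = c("easy", "hard"), seed = 1L,
                         ar = c(1.45, -0.475), noise_sd = 10,
                         class_freqs = c(4, 10, 16, 24, 32),
                         base_amp = NULL, amp_jitter_sd = NULL,
                         burst_amp_factor = NULL) {
  difficulty <- match.arg(difficulty)
  if (n_classes < 2L) stop("invalid config: n_classes must be >= 2")
  if (length < 512L) stop("invalid config: length must be >= 512")
  if (records_per_class < 1L) stop("invalid config: need records_per_class >= 1")
  easy <- difficulty == "easy"
  structure(list(
    n_classes = as.integer(n_classes),
    records_per_class = as.integer(records_per_class),
    length = as.integer(length), fs = fs, difficulty = difficulty,
    seed = as.integer(seed), ar = ar, noise_sd = noise_sd,
    class_freqs = rep_len(class_freqs, n_classes),
    base_amp = if (is.null(base_amp)) (if (easy) 25 else 7) else base_amp,
    amp_jitter_sd = if (is.null(amp_jitter_sd)) (if (easy) 1.5 else 5)
                    else amp_jitter_sd,
    burst_amp_factor = if (is.null(burst_amp_factor)) (if (easy) 5 else 2)
                       else burst_amp_factor),
    class = "synth_config")
}

spike_burst <- function(n, fs, amp) {
  # ~3 Hz spike train shaped by Gaussian bumps, alternating polarity
  t <- seq_len(n) / fs
  period <- 1 / 3
  centers <- seq(period / 2, max(t), by = period)
  y <- numeric(n)
  for (i in seq_along(centers))
    y <- y + (-1)^(i + 1) * amp * exp(-((t - centers[i]) / 0.03)^2)
  y
}

generate_record <- function(cfg, class_idx, rec_idx) {
  L <- cfg$length
  base <- as.numeric(arima.sim(model = list(ar = cfg$ar), n = L,
                               sd = cfg$noise_sd))
  f <- cfg$class_freqs[class_idx + 1L]
  amp <- max(0, cfg$base_amp * (1 + 0.3 * class_idx) +
               rnorm(1, sd = cfg$amp_jitter_sd))
  phase <- runif(1, 0, 2 * pi)
  t <- seq_len(L) / cfg$fs
  x <- base + amp * sin(2 * pi * f * t + phase)
  if (class_idx == cfg$n_classes - 1L) {
    n_bursts <- sample(3:6, 1)
    burst_len <- round(cfg$fs) # ~1 s
    b_amp <- cfg$burst_amp_factor * sd(base)
    for (b in seq_len(n_bursts)) {
      onset <- sample.int(L - burst_len, 1)
      idx <- onset:(onset + burst_len - 1L)
      x[idx] <- x[idx] + spike_burst(burst_len, cfg$fs, b_amp)
    }
  }
  lab <- LETTERS[class_idx + 1L]
  eeg_record(x, fs = cfg$fs, set_label = lab,
             record_id = sprintf("%s_%03d", lab, rec_idx))
}

#' Generate a labeled synthetic dataset
#'
#' Fully seeded: the same configuration yields bitwise-identical records.
#'
#' @param cfg a [synth_config()].
#' @return list of [eeg_record()], grouped by class.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    out <- vector("list", cfg$n_classes * cfg$records_per_class)
    i <- 0L
    for (cl in seq_len(cfg$n_classes) - 1L)
      for (r in seq_len(cfg$records_per_class)) {
        i <- i + 1L
        out[[i]] <- generate_record(cfg, cl, r)
      }
    out
  })
}

#' Write records as a Bonn-format directory tree
#'
#' One subdirectory per set label, one ASCII file per record.  By default
#' samples are rounded to integers, matching the integer ADC counts of the
#' original corpus format; pass `round = FALSE` to keep full precision.
#'
#' @param records list of [eeg_record()].
#' @param dir output directory (created if needed).
#' @param round round samples to integers before writing.
#' @return `dir`, invisibly.
#' @export
write_bonn_dataset <- function(records, dir, round = TRUE) {
  for (r in records) {
    sub <- file.path(dir, r$set_label)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    fname <- paste0(sub("^.*:", "", r$record_id), ".txt")
    write_bonn_record(r, file.path(sub, fname), round = round)
  }
  invisible(dir)
}

#' Closed-form band-power features for separability checks
#'
#' Per record: log periodogram power inside a +/- `half_width` Hz band
#' around each supplied center frequency, plus the log total variance.
#' These features are a network-independent oracle: if a linear classifier
#' on them separates the classes, the dataset is separable by design.
#'
#' @param records list of [eeg_record()].
#' @param freqs band center frequencies in Hz.
#' @param half_width band half-width in Hz.
#' @return numeric matrix, one row per record.
#' @export
band_power_features <- function(records, freqs, half_width = 2) {
  feats <- t(vapply(records, function(r) {
    L <- length(r$samples)
    P <- Mod(fft(r$samples - mean(r$samples)))^2 / L
    fgrid <- (seq_len(L) - 1L) * r$fs / L
    half <- seq_len(L %/% 2L)
    bp <- vapply(freqs, function(f)
      sum(P[half][abs(fgrid[half] - f) <= half_width]), numeric(1))
    c(log(bp + 1e-12), log(var(r$samples)))
  }, numeric(length(freqs) + 1L)))
  colnames(feats) <- c(paste0("band_", freqs, "Hz"), "log_var")
  feats
}
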
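# Synthetic FPVS-EEG generator. A recording is the sum of
#   (a) a base-rate periodic response: harmonics of the base frequency with
#       geometric amplitude decay and a medial-occipital topography,
#   (b) an oddball response: harmonics of the oddball frequency excluding
#       bins coinciding with base harmonics, occipito-temporal and
#       right-lateralized topography, amplitude set by group x condition,
#   (c) 1/f-shaped Gaussian background noise,
#   (d) an alpha sinusoid (~10 Hz) with random phase per sequence,
#   (e) optional stereotyped blinks.
# All injected harmonics share zero phase at sequence onset; the
# frequency-domain statistics downstream are phase-insensitive.

# Gaussian topography gains on the unit sphere: sum of Gaussian bumps in
# chord distance around named centre electrodes, peak-normalized to 1.
.topo_gauss <- function(labels, centers, weights, width) {
  pos <- biosemi64_montage(labels)
  cpos <- biosemi64_montage(centers)
  g <- rep(0, length(labels))
  for (i in seq_along(centers)) {
    d2 <- (pos$x - cpos$x[i])^2 + (pos$y - cpos$y[i])^2 + (pos$z - cpos$z[i])^2
    g <- g + weights[i] * exp(-d2 / width^2)
  }
  g / max(g)
}

.topo_base  <- function(labels) .topo_gauss(labels, c("Oz", "Iz"), c(1, 0.9), 0.55)
.topo_odd   <- function(labels) .topo_gauss(labels, c("PO8", "PO7"), c(1, 0.8), 0.5)
.topo_alpha <- function(labels) .topo_gauss(labels, "POz", 1, 0.9)
.topo_blink <- function(labels) .topo_gauss(labels, "Fpz", 1, 0.7)

#' Generate 1/f-shaped Gaussian noise
#'
#' Frequency-domain shaping of white Gaussian noise: a Hermitian random
#' spectrum with amplitude proportional to `f^(-exponent/2)` (power spectral
#' density 1/f^exponent) is inverse-transformed; the DC bin is zero. The
#' output is scaled analytically so that each channel has expected RMS
#' `rms`.
#'
#' @param n Samples per channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param exponent Spectral exponent (0 = white, 1 = pink).
#' @param rms Target RMS amplitude per channel.
#' @param n_channels Number of independent channels.
#' @return `n_channels x n` numeric matrix.
#' @export
noise_1f <- function(n, sampling_rate, exponent = 1, rms = 1, n_channels = 1) {
  if (rms == 0 || n < 2) return(matrix(0, n_channels, n))
  half <- floor((n - 1) / 2)              # strictly-positive, non-Nyquist bins
  f <- (1:half) * sampling_rate / n
  w <- f^(-exponent / 2)
  has_nyq <- n %% 2 == 0
  wn <- if (has_nyq) (sampling_rate / 2)^(-exponent / 2) else numeric(0)
  # expected variance of ifft-synthesized series before scaling
  ev <- (2 * sum(w^2) + sum(wn^2)) / n^2
  sc <- rms / sqrt(ev)
  out <- matrix(0, n_channels, n)
  Z <- matrix(0 + 0i, n, n_channels)
  for (ch in seq_len(n_channels)) {
    z <- w * complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) /
      sqrt(2)
    Z[2:(half + 1), ch] <- z
    Z[n:(n - half + 1), ch] <- Conj(z)
    if (has_nyq) Z[n / 2 + 1, ch] <- wn * stats::rnorm(1)
  }
  out <- t(Re(stats::mvfft(Z, inverse = TRUE))) / n * sc
  out
}

# contrast envelope of one stimulation sequence, sampled at fs:
# sinusoidal fade-in, full contrast, sinusoidal fade-out
.sequence_envelope <- function(t, fade, full) {
  env <- rep(0, length(t))
  total <- 2 * fade + full
  inseq <- t >= 0 & t < total
  env[inseq] <- 1
  if (fade > 0) {
    i <- t >= 0 & t < fade
    env[i] <- sin(pi * t[i] / (2 * fade))^2
    i <- t >= (fade + full) & t < total
    env[i] <- sin(pi * (total - t[i]) / (2 * fade))^2
  }
  env
}

#' Simulate one subject's FPVS-EEG recording
#'
#' Produces a continuous multi-channel recording containing, per condition,
#' `n_sequences_per_condition` stimulation sequences with event markers at
#' sequence onsets, together with the injected ground-truth amplitudes.
#'
#' @param config An [sim_config()] object.
#' @param group Group label (one of `config$groups`).
#' @param seed Integer seed for this subject.
#' @param subject_id Subject identifier string.
#' @return A list with elements `recording` (class `fpvs_recording`:
#'   `data` channels x samples in µV, `sampling_rate`, `channel_labels`,
#'   `events` data.frame with `sample` and `condition`, `subject_id`,
#'   `group`) and `ground_truth` (per condition, the channels x harmonics
#'   matrices of injected oddball and base amplitudes plus their
#'   frequencies and the subject gains).
#' @export
simulate_subject <- function(config, group, seed = config$seed,
                             subject_id = paste0(group, "_1")) {
  validate_sim_config(config)
  if (!group %in% config$groups)
    stop("unknown group label: ", group)
  fs <- config$sampling_rate
  labels <- config$channel_labels
  nch <- length(labels)
  set.seed(as.integer(seed))

  # per-subject response gain, shared across conditions (log-normal)
  g_odd <- exp(stats::rnorm(1, 0, config$subject_sd))
  g_base <- exp(stats::rnorm(1, 0, config$subject_sd))

  block_n <- round((config$epoch_pre + config$epoch_post) * fs)
  conds <- rep(config$conditions, each = config$n_sequences_per_condition)
  conds <- sample(conds)                      # randomized sequence order
  n_blocks <- length(conds)
  total_n <- n_blocks * block_n
  onset_offset <- round(config$epoch_pre * fs)

  f_odd <- oddball_harmonic_freqs(config$oddball_freq, config$base_freq,
                                  config$n_harmonics)
  f_base <- config$base_freq * seq_len(config$n_base_harmonics)
  decay_o <- config$harmonic_decay^(seq_along(f_odd) - 1)
  decay_b <- config$harmonic_decay^(seq_along(f_base) - 1)
  tp <- config$topographies
  topo_o <- if (!is.null(tp$oddball)) tp$oddball else .topo_odd(labels)
  topo_b <- if (!is.null(tp$base)) tp$base else .topo_base(labels)
  topo_a <- if (!is.null(tp$alpha)) tp$alpha else .topo_alpha(labels)

  data <- noise_1f(total_n, fs, config$noise_1f_exponent, config$noise_scale,
                   nch)

  # stimulation waveforms: one per condition, shared across that
  # condition's sequences (zero phase at onset)
  t_seq <- (seq_len(block_n) - 1) / fs - config$epoch_pre
  env <- .sequence_envelope(t_seq, config$fade_duration, config$full_duration)
  base_amps <- config$base_amp * decay_b * g_base
  wave_base <- env * colSums(base_amps *
    t(sin(2 * pi * outer(t_seq, f_base))))
  wave_odd_c <- list()
  for (cond in config$conditions) {
    a1 <- config$oddball_amp[[group]][[cond]]
    if (is.null(a1)) stop("oddball_amp has no entry for ", group, "/", cond)
    amps <- a1 * decay_o * g_odd
    wave_odd_c[[cond]] <- env * colSums(amps *
      t(sin(2 * pi * outer(t_seq, f_odd))))
  }

  events <- data.frame(sample = integer(n_blocks),
                       condition = conds, stringsAsFactors = FALSE)
  for (b in seq_len(n_blocks)) {
    idx <- (b - 1) * block_n + seq_len(block_n)
    events$sample[b] <- (b - 1) * block_n + onset_offset + 1L
    if (config$alpha_amp > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      alpha <- config$alpha_amp * sin(2 * pi * config$alpha_freq * t_seq + ph)
      data[, idx] <- data[, idx] + outer(topo_a, alpha)
    }
    data[, idx] <- data[, idx] + outer(topo_b, wave_base) +
      outer(topo_o, wave_odd_c[[conds[b]]])
  }

  rec <- structure(list(data = data,
                        sampling_rate = fs,
                        channel_labels = labels,
                        events = events,
                        subject_id = subject_id,
                        group = group),
                   class = "fpvs_recording")
  if (config$blink_rate > 0)
    rec <- inject_blinks(rec, config$blink_rate, seed = seed + 1L,
                         amp = config$blink_amp,
                         topography = tp$blink)

  gt_odd <- lapply(config$conditions, function(cond) {
    a1 <- config$oddball_amp[[group]][[cond]]
    outer(topo_o, a1 * decay_o * g_odd)
  })
  names(gt_odd) <- config$conditions
  gt <- list(oddball = gt_odd,
             base = outer(topo_b, base_amps),
             oddball_freqs = f_odd,
             base_freqs = f_base,
             gain_oddball = g_odd,
             gain_base = g_base,
             channel_labels = labels)
  list(recording = rec, ground_truth = gt)
}

#' Simulate a balanced two-group cohort
#'
#' Subject seeds are derived deterministically from `config$seed`, so the
#' same configuration always yields a bit-identical cohort.
#'
#' @param config An [sim_config()] object.
#' @return List of per-subject results as returned by [simulate_subject()],
#'   groups interleaved; `2 * n_per_group` elements.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  out <- vector("list", 2 * config$n_per_group)
  k <- 0
  for (i in seq_len(config$n_per_group)) {
    for (g in config$groups) {
      k <- k + 1
      out[[k]] <- simulate_subject(
        config, g, seed = config$seed + 131L * k,
        subject_id = sprintf("%s_%02d", g, i))
    }
  }
  out
}

#' Add stereotyped blinks to a recording
#'
#' Blinks are half-cosine transients (duration ~0.35 s) with a
#' frontal-dominant topography, placed at the times of a homogeneous
#' Poisson process over the whole recording.
#'
#' @param recording An `fpvs_recording`.
#' @param rate Blink rate in events/s (0 returns the recording unchanged).
#' @param seed Integer seed.
#' @param amp Peak amplitude at the frontal maximum, µV.
#' @param duration Blink duration in s.
#' @param topography Optional per-channel gain vector (defaults to the
#'   built-in frontal-dominant map).
#' @return The recording with blinks added; the number of injected blinks
#'   is stored in `recording$n_blinks` and their onset samples in
#'   `recording$blink_onsets`.
#' @export
inject_blinks <- function(recording, rate, seed = 1L, amp = 100,
                          duration = 0.35, topography = NULL) {
  stopifnot(inherits(recording, "fpvs_recording"), rate >= 0)
  if (rate == 0) {
    recording$n_blinks <- 0L
    return(recording)
  }
  set.seed(as.integer(seed))
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  dur_s <- n / fs
  n_blinks <- stats::rpois(1, rate * dur_s)
  kern_n <- round(duration * fs)
  kern <- amp * sin(pi * (seq_len(kern_n) - 1) / (kern_n - 1))
  topo <- if (!is.null(topography)) topography
          else .topo_blink(recording$channel_labels)
  onsets <- sort(sample.int(max(1L, n - kern_n), n_blinks, replace = TRUE))
  for (s in onsets) {
    idx <- s + seq_len(kern_n) - 1L
    recording$data[, idx] <- recording$data[, idx] + outer(topo, kern)
  }
  recording$n_blinks <- n_blinks
  recording$blink_onsets <- onsets
  recording
}

#' @export
print.fpvs_recording <- function(x, ...) {
  cat(sprintf("FPVS recording: %s (group %s)\n", x$subject_id, x$group))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s), %d sequence markers\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, nrow(x$events)))
  if (!is.null(x$n_blinks)) cat(sprintf("  %d injected blinks\n", x$n_blinks))
  invisible(x)
}
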